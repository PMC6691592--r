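#' Create an empty linear latent-variable model specification
#'
#' A model specification lists observed and latent variables together with
#' three labelled parameter tables in the reticular (RAM) convention:
#' directed paths (regressions and loadings, the \code{A} matrix), undirected
#' parameters (variances and covariances, the \code{S} matrix) and mean
#' parameters (intercepts and latent means, the \code{m} vector). Every
#' parameter row carries a label; rows sharing a label and marked free are
#' constrained to be equal. Fixed rows keep their label so constraints can be
#' edited later with [edit_constraint()].
#'
#' @param observed character vector of observed-variable names, in the order
#'   the data columns are expected.
#' @param latent character vector of latent-variable names.
#' @return An object of class \code{model_spec}.
#' @seealso [add_path()], [add_cov()], [add_mean()], [edit_constraint()]
#' @export
model_spec <- function(observed, latent = character()) {
  stopifnot(is.character(observed), length(observed) >= 1)
  all_vars <- c(observed, latent)
  if (anyDuplicated(all_vars)) {
    stop("variable names must be unique across observed and latent variables")
  }
  structure(
    list(
      variables = data.frame(
        name = all_vars,
        latent = rep(c(FALSE, TRUE), c(length(observed), length(latent))),
        stringsAsFactors = FALSE
      ),
      paths = empty_param_table(c("from", "to")),
      covs  = empty_param_table(c("v1", "v2")),
      means = empty_param_table("variable")
    ),
    class = "model_spec"
  )
}

empty_param_table <- function(key_cols) {
  cols <- c(stats::setNames(rep(list(character()), length(key_cols)), key_cols),
            list(label = character(), value = numeric(), free = logical()))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

check_vars <- function(spec, vars) {
  bad <- setdiff(vars, spec$variables$name)
  if (length(bad)) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  }
}

#' Add a directed path (regression or loading) to a model specification
#'
#' @param spec a [model_spec()].
#' @param from,to variable names; the path points \code{from -> to}.
#' @param label parameter label. Rows sharing a label are equality-constrained
#'   when free. If \code{NULL} an automatic label is generated.
#' @param value starting value (free parameters) or fixed constant.
#' @param free logical; free parameter or fixed constant.
#' @return The modified specification.
#' @export
add_path <- function(spec, from, to, label = NULL, value = 0, free = !is.null(label)) {
  check_vars(spec, c(from, to))
  if (is.null(label)) label <- paste0(to, "~", from)
  spec$paths <- rbind(spec$paths, data.frame(
    from = from, to = to, label = label, value = value, free = free,
    stringsAsFactors = FALSE
  ))
  spec
}

#' Add a variance or covariance parameter to a model specification
#'
#' @inheritParams add_path
#' @param v1,v2 variable names; \code{v1 == v2} declares a (residual) variance.
#' @return The modified specification.
#' @export
add_cov <- function(spec, v1, v2, label = NULL, value = 0, free = !is.null(label)) {
  check_vars(spec, c(v1, v2))
  if (is.null(label)) label <- paste0(v1, "~~", v2)
  spec$covs <- rbind(spec$covs, data.frame(
    v1 = v1, v2 = v2, label = label, value = value, free = free,
    stringsAsFactors = FALSE
  ))
  spec
}

#' Add a mean or intercept parameter to a model specification
#'
#' @inheritParams add_path
#' @param variable variable name.
#' @return The modified specification.
#' @export
add_mean <- function(spec, variable, label = NULL, value = 0, free = !is.null(label)) {
  check_vars(spec, variable)
  if (is.null(label)) label <- paste0(variable, "~1")
  spec$means <- rbind(spec$means, data.frame(
    variable = variable, label = label, value = value, free = free,
    stringsAsFactors = FALSE
  ))
  spec
}

all_param_rows <- function(spec) {
  grab <- function(tab, nm) {
    data.frame(matrix = rep(nm, nrow(tab)), label = tab$label,
               value = tab$value, free = tab$free, stringsAsFactors = FALSE)
  }
  rbind(grab(spec$paths, "paths"), grab(spec$covs, "covs"),
        grab(spec$means, "means"))
}

#' Free parameters of a specification
#'
#' @param spec a [model_spec()].
#' @return A data frame with one row per distinct free label: \code{label} and
#'   its starting \code{value}.
#' @export
free_params <- function(spec) {
  rows <- all_param_rows(spec)
  rows <- rows[rows$free, , drop = FALSE]
  rows <- rows[!duplicated(rows$label), c("label", "value")]
  rownames(rows) <- NULL
  rows
}

#' Number of distinct free parameters
#' @param spec a [model_spec()].
#' @return Integer count of distinct free labels.
#' @export
n_free <- function(spec) nrow(free_params(spec))

#' Model degrees of freedom against the saturated mean-and-covariance model
#'
#' With \code{p} observed variables the saturated model has
#' \code{p(p+1)/2} covariances plus \code{p} means; the model df is that
#' count minus the number of distinct free parameters.
#'
#' @param spec a [model_spec()].
#' @param n_groups number of groups the model is fitted to simultaneously.
#' @return Integer degrees of freedom.
#' @export
spec_df <- function(spec, n_groups = 1L) {
  p <- sum(!spec$variables$latent)
  n_groups * (p * (p + 1) / 2 + p) - n_free(spec)
}

#' Edit the constraint structure of a specification
#'
#' Supports the nested-model tests used throughout the analysis: freeing a
#' fixed parameter, fixing a parameter to a constant, and equating a set of
#' free parameters under a common label.
#'
#' @param spec a [model_spec()].
#' @param action one of \code{"free"}, \code{"fix"}, \code{"equate"}.
#' @param targets character vector of parameter labels.
#' @param value constant for \code{"fix"} (required) or optional new starting
#'   value for \code{"free"}.
#' @return A new specification; the input is not modified.
#' @export
edit_constraint <- function(spec, action = c("free", "fix", "equate"),
                            targets, value = NULL) {
  action <- match.arg(action)
  known <- unique(all_param_rows(spec)$label)
  bad <- setdiff(targets, known)
  if (length(bad)) {
    stop("unknown parameter label(s): ", paste(bad, collapse = ", "),
         "\navailable labels: ", paste(known, collapse = ", "))
  }
  apply_tab <- function(tab) {
    hit <- tab$label %in% targets
    if (!any(hit)) return(tab)
    if (action == "free") {
      tab$free[hit] <- TRUE
      if (!is.null(value)) tab$value[hit] <- value
    } else if (action == "fix") {
      if (is.null(value)) stop("'fix' requires a value")
      tab$free[hit] <- FALSE
      tab$value[hit] <- value
    } else { # equate
      tab$label[hit] <- targets[1]
      tab$free[hit] <- TRUE
    }
    tab
  }
  spec$paths <- apply_tab(spec$paths)
  spec$covs <- apply_tab(spec$covs)
  spec$means <- apply_tab(spec$means)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  p <- sum(!x$variables$latent)
  cat("Linear latent-variable model specification\n")
  cat(sprintf("  observed: %d, latent: %d\n", p, sum(x$variables$latent)))
  cat(sprintf("  free parameters: %d, df: %d\n", n_free(x), spec_df(x)))
  invisible(x)
}

#' Serialize a model specification to a human-readable text form
#'
#' The format is a sequence of tab-separated tables (variables, paths,
#' covariances, means) that [spec_from_text()] parses back. Intended for
#' auditing model structure and archiving fitted specifications.
#'
#' @param spec a [model_spec()].
#' @param path optional file to write to.
#' @return The text representation, invisibly when written to a file.
#' @export
spec_to_text <- function(spec, path = NULL) {
  fmt_tab <- function(name, tab) {
    rows <- if (nrow(tab)) do.call(paste, c(unname(as.list(tab)), sep = "\t")) else character()
    c(paste0("[", name, "]"), paste(colnames(tab), collapse = "\t"), rows)
  }
  vars <- spec$variables
  lines <- c(
    fmt_tab("variables", data.frame(name = vars$name, latent = vars$latent)),
    fmt_tab("paths", spec$paths),
    fmt_tab("covs", spec$covs),
    fmt_tab("means", spec$means)
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse a model specification from its text form
#'
#' @param text character scalar as produced by [spec_to_text()], or \code{NULL}
#'   to read from \code{path}.
#' @param path file to read when \code{text} is \code{NULL}.
#' @return A [model_spec()].
#' @export
spec_from_text <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^\\[", lines)
  blocks <- list()
  for (i in seq_along(starts)) {
    name <- gsub("\\[|\\]", "", lines[starts[i]])
    end <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    body <- lines[(starts[i] + 1):end]
    body <- body[nzchar(body)]
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    if (length(body) > 1) {
      cells <- do.call(rbind, strsplit(body[-1], "\t", fixed = TRUE))
      tab <- as.data.frame(cells, stringsAsFactors = FALSE)
      colnames(tab) <- header
    } else {
      tab <- as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                           header), stringsAsFactors = FALSE)
    }
    blocks[[name]] <- tab
  }
  vars <- blocks$variables
  vars$latent <- as.logical(vars$latent)
  spec <- model_spec(observed = vars$name[!vars$latent],
                     latent = vars$name[vars$latent])
  num <- function(tab) {
    tab$value <- as.numeric(tab$value)
    tab$free <- as.logical(tab$free)
    tab
  }
  if (nrow(blocks$paths)) spec$paths <- num(blocks$paths)
  if (nrow(blocks$covs)) spec$covs <- num(blocks$covs)
  if (nrow(blocks$means)) spec$means <- num(blocks$means)
  spec
}
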