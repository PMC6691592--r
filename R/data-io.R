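#' Construct a longitudinal score dataset
#'
#' Holds per-person test scores for a waves-by-domains design in a single
#' wide matrix. Columns are named \code{<domain>_t<wave>} (e.g.
#' \code{voc_t1}), domain-major within wave order is not required as long as
#' all \code{waves * domains} columns are present. Missing scores are
#' \code{NA}.
#'
#' @param scores numeric matrix or data frame, persons in rows; column names
#'   must be the canonical \code{<domain>_t<wave>} names.
#' @param wave_labels ordered character vector of wave labels.
#' @param domain_labels ordered character vector of domain labels.
#' @param group optional per-person grouping factor (e.g. gender).
#' @param person_id optional person identifiers; defaults to row numbers.
#' @return An object of class \code{lcs_data}.
#' @export
longitudinal_data <- function(scores, wave_labels, domain_labels,
                              group = NULL, person_id = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  expected <- canonical_names(domain_labels, length(wave_labels))
  missing_cols <- setdiff(expected, colnames(scores))
  if (length(missing_cols)) {
    stop("missing score columns: ", paste(missing_cols, collapse = ", "))
  }
  scores <- scores[, expected, drop = FALSE]
  if (nrow(scores) == 0) stop("dataset has no persons")
  if (!is.null(group)) {
    group <- as.factor(group)
    stopifnot(length(group) == nrow(scores))
  }
  if (is.null(person_id)) person_id <- seq_len(nrow(scores))
  stopifnot(length(person_id) == nrow(scores))
  empty <- rowSums(!is.na(scores)) == 0
  if (any(empty)) {
    warning(sum(empty), " person(s) have no observed scores; ",
            "they carry no information and are dropped from likelihoods")
  }
  structure(
    list(scores = scores, wave_labels = wave_labels,
         domain_labels = domain_labels, group = group,
         person_id = person_id, all_missing = empty),
    class = "lcs_data"
  )
}

canonical_names <- function(domains, n_waves) {
  as.vector(t(outer(domains, seq_len(n_waves),
                    function(d, w) paste0(d, "_t", w))))
}

#' @export
print.lcs_data <- function(x, ...) {
  cat(sprintf("Longitudinal dataset: %d persons, %d waves x %d domains (%d variables)\n",
              nrow(x$scores), length(x$wave_labels), length(x$domain_labels),
              ncol(x$scores)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$scores)),
              100 * mean(is.na(x$scores))))
  if (!is.null(x$group)) {
    cat("  groups:", paste(levels(x$group), table(x$group),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.lcs_data <- function(x, ...) {
  out <- data.frame(person_id = x$person_id, x$scores,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(x$group)) out$group <- x$group
  out
}

#' Read a wide-format longitudinal score table from CSV
#'
#' @param path CSV file with a header row.
#' @param column_map data frame with columns \code{column}, \code{wave}
#'   (integer occasion index), \code{domain} (domain label), mapping CSV score
#'   columns to the design; or a named character vector
#'   \code{c(CSVcol = "<domain>_t<wave>")}.
#' @param wave_labels,domain_labels design labels; inferred from the map when
#'   omitted.
#' @param missing_tokens cell contents treated as missing (default empty cell
#'   and \code{"NA"}).
#' @param id_col,group_col optional names of identifier and grouping columns.
#' @return An \code{lcs_data} object. A per-variable validation report
#'   (observed and missing counts) is attached as attribute
#'   \code{"validation"}.
#' @export
read_wide_csv <- function(path, column_map, wave_labels = NULL,
                          domain_labels = NULL,
                          missing_tokens = c("", "NA"),
                          id_col = NULL, group_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0) stop("empty file (no data rows): ", path)
  if (is.data.frame(column_map)) {
    stopifnot(all(c("column", "wave", "domain") %in% colnames(column_map)))
    target <- paste0(column_map$domain, "_t", column_map$wave)
    names(target) <- column_map$column
    column_map <- target
  }
  absent <- setdiff(names(column_map), colnames(raw))
  if (length(absent)) {
    stop("configuration error: mapped column(s) not in file: ",
         paste(absent, collapse = ", "))
  }
  waves <- as.integer(sub("^.*_t", "", unname(column_map)))
  domains <- sub("_t[0-9]+$", "", unname(column_map))
  if (is.null(domain_labels)) domain_labels <- unique(domains)
  if (is.null(wave_labels)) wave_labels <- paste0("T", sort(unique(waves)))
  expected <- canonical_names(domain_labels, length(wave_labels))
  if (!setequal(unname(column_map), expected)) {
    stop("configuration error: column map does not cover waves x domains; ",
         "expected targets: ", paste(expected, collapse = ", "))
  }
  scores <- matrix(NA_real_, nrow(raw), length(column_map),
                   dimnames = list(NULL, unname(column_map)))
  for (j in seq_along(column_map)) {
    cells <- raw[[names(column_map)[j]]]
    is_missing <- is.na(cells) | cells %in% missing_tokens
    num <- suppressWarnings(as.numeric(cells))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                   cells[which(bad)[1]], names(column_map)[j], which(bad)[1]))
    }
    num[is_missing] <- NA_real_
    scores[, j] <- num
  }
  group <- if (!is.null(group_col)) raw[[group_col]] else NULL
  pid <- if (!is.null(id_col)) raw[[id_col]] else NULL
  dat <- longitudinal_data(scores, wave_labels, domain_labels,
                           group = group, person_id = pid)
  attr(dat, "validation") <- data.frame(
    variable = colnames(dat$scores),
    n_observed = colSums(!is.na(dat$scores)),
    n_missing = colSums(is.na(dat$scores)),
    row.names = NULL
  )
  dat
}

#' Write a longitudinal dataset to wide CSV
#'
#' Writes the same dialect [read_wide_csv()] consumes (canonical column
#' names, empty cells for missing scores), so a read/write/read round trip is
#' lossless.
#'
#' @param data an \code{lcs_data} object.
#' @param path output file.
#' @param missing_token string written for missing cells.
#' @return \code{path}, invisibly.
#' @export
write_wide_csv <- function(data, path, missing_token = "") {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, na = missing_token)
  invisible(path)
}

#' Per-variable descriptive statistics
#'
#' @param data an \code{lcs_data} object.
#' @return A data frame with one row per observed variable (n, mean, sample
#'   variance with the n-1 divisor, missing count; variance is \code{NA} and
#'   flagged when fewer than two observations are available). The
#'   pairwise-complete sample covariance matrix is attached as attribute
#'   \code{"cov"}.
#' @export
describe <- function(data) {
  stopifnot(inherits(data, "lcs_data"))
  sc <- data$scores
  n_obs <- colSums(!is.na(sc))
  out <- data.frame(
    variable = colnames(sc),
    n = n_obs,
    mean = colMeans(sc, na.rm = TRUE),
    variance = apply(sc, 2, function(v) {
      if (sum(!is.na(v)) < 2) NA_real_ else stats::var(v, na.rm = TRUE)
    }),
    n_missing = colSums(is.na(sc)),
    row.names = NULL
  )
  out$flag <- ifelse(n_obs < 2, "variance undefined (<2 observations)", "")
  attr(out, "cov") <- stats::cov(sc, use = "pairwise.complete.obs")
  out
}

#' Read a study configuration file
#'
#' YAML configuration naming the column map and optional analysis inputs:
#' \preformatted{
#' column_map: {Voc_W2: voc_t1, Voc_W3: voc_t2, ...}
#' domains: [voc, mat]
#' reliabilities: {voc: [0.9, 0.9, 0.9], mat: [0.85, 0.85, 0.85]}
#' missing_tokens: ["", "NA"]
#' }
#'
#' @param path YAML file.
#' @return A named list of configuration entries.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$column_map)) cfg$column_map <- unlist(cfg$column_map)
  cfg
}
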