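# Tabular I/O. All files are TSV with headers, UTF-8, '.' decimal; numbers
# are written with "%.17g" so a write/read round trip is exact in double
# precision (the per-factor results table is the one deliberate exception,
# emitted at 6 significant digits).

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_impl <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_full)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read an effect panel from a TSV file
#'
#' Accepts either precomputed estimates (columns `id, beta, se`) or raw 2x2
#' counts (columns `id, a, b, c, d`), in which case [crude_logor()] is
#' applied row by row.
#'
#' @param path TSV file with a header row.
#' @param haldane Passed to [crude_logor()] for the counts layout.
#' @return An [effect_panel()].
#' @export
read_panel <- function(path, haldane = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) {
    stop("panel file ", path, " must have an 'id' column", call. = FALSE)
  }
  if (all(c("beta", "se") %in% names(df))) {
    effect_panel(df$beta, df$se, labels = df$id)
  } else if (all(c("a", "b", "c", "d") %in% names(df))) {
    est <- lapply(seq_len(nrow(df)), function(i) {
      crude_logor(two_by_two(df$a[i], df$b[i], df$c[i], df$d[i]),
                  haldane = haldane)
    })
    effect_panel(vapply(est, `[[`, numeric(1), "beta"),
                 vapply(est, `[[`, numeric(1), "se"),
                 labels = df$id)
  } else {
    stop("panel file ", path,
         " needs columns id, beta, se  or  id, a, b, c, d", call. = FALSE)
  }
}

#' Write an effect panel as TSV (`id, beta, se`)
#'
#' @param panel An [effect_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "effect_panel"))
  write_tsv_impl(data.frame(id = panel$labels, beta = unname(panel$beta),
                            se = unname(panel$se), stringsAsFactors = FALSE),
                 path)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' First column and header row carry matching labels.
#'
#' @param path TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square", call. = FALSE)
  dimnames(m) <- list(labels, colnames(df)[-1])
  m
}

#' Write a labelled square matrix as TSV
#'
#' @param m Square numeric matrix (dimnames used as labels).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_square_matrix <- function(m, path) {
  labels <- rownames(m) %||% paste0("V", seq_len(nrow(m)))
  df <- data.frame(id = labels, as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", labels)
  write_tsv_impl(df, path)
  invisible(path)
}

#' Read a simulation scenario from a flat key=value config file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognized keys: `K, tau2, sigma2_mean, correlation, effect_dist, reps,
#' level, seed`.
#'
#' @param path Config file path.
#' @return A validated [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("cannot parse config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  vals <- stats::setNames(vapply(kv, `[`, character(1), 3),
                          vapply(kv, `[`, character(1), 2))
  get_num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  get_chr <- function(key, default) {
    if (key %in% names(vals)) vals[[key]] else default
  }
  known <- c("K", "tau2", "sigma2_mean", "correlation", "effect_dist",
             "reps", "level", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "), call. = FALSE)
  }
  scenario_config(K = get_num("K", 100), tau2 = get_num("tau2", 1),
                  sigma2_mean = get_num("sigma2_mean", 0.25),
                  correlation = get_chr("correlation", "independent"),
                  effect_dist = get_chr("effect_dist", "normal"),
                  reps = get_num("reps", 10000),
                  level = get_num("level", 0.95),
                  seed = get_num("seed", 1))
}

#' Write coverage results as long-format TSV
#'
#' @param df Data frame from [scenario_grid()] (or a single
#'   `coverage_result` coerced via its row form).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_results <- function(df, path) {
  if (inherits(df, "coverage_result")) df <- coverage_result_row(df)
  write_tsv_impl(df, path)
  invisible(path)
}

# per-factor results table at 6 significant digits (interface contract)
write_results_table <- function(tab, path) {
  out <- tab
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.6g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
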