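# Serialisation: judgment matrices as JSON (fraction strings preserved so
# round-trips are exact), hierarchies as YAML/JSON, reports as text/JSON.

#' Read and write judgment matrices as JSON
#'
#' Layout: `{"labels": [...], "entries": [[...], ...]}` where each entry is
#' a number or a fraction string such as `"1/7"`. Writing always emits
#' fraction strings for non-integer entries, so a read/write cycle
#' reproduces the rational entries exactly.
#'
#' @param m A [judgment_matrix()].
#' @param path File path.
#' @param validate,strict_scale Passed to [judgment_matrix()] on read.
#' @return `read_judgment_matrix` returns a `judgment_matrix`;
#'   `write_judgment_matrix` returns `path` invisibly.
#' @export
write_judgment_matrix <- function(m, path) {
  stopifnot(inherits(m, "judgment_matrix"))
  n <- nrow(m$num)
  entries <- lapply(seq_len(n), function(i) {
    lapply(seq_len(n), function(j) {
      if (m$den[i, j] == 1L) m$num[i, j] else paste0(m$num[i, j], "/", m$den[i, j])
    })
  })
  jsonlite::write_json(list(labels = m$labels, entries = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_judgment_matrix
#' @export
read_judgment_matrix <- function(path, validate = TRUE, strict_scale = FALSE) {
  x <- jsonlite::read_json(path)
  rows <- lapply(x$entries, function(r) lapply(r, identity))
  judgment_matrix(rows, labels = unlist(x$labels), validate = validate,
                  strict_scale = strict_scale)
}

#' Read and write AHP hierarchies as YAML or JSON
#'
#' Layout: `goal`, either `criteria_matrix` (a judgment-matrix mapping with
#' `labels` + `entries`) or `criterion_weights` (a name-to-weight mapping),
#' and `alternatives` (one judgment-matrix mapping per criterion). Format is
#' chosen by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param h An [hierarchy()].
#' @param path File path.
#' @return `read_hierarchy` returns an `ahp_hierarchy`; `write_hierarchy`
#'   returns `path` invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  jm_to_list <- function(m) {
    n <- nrow(m$num)
    list(labels = as.list(m$labels),
         entries = lapply(seq_len(n), function(i) {
           lapply(seq_len(n), function(j) {
             if (m$den[i, j] == 1L) m$num[i, j] else paste0(m$num[i, j], "/", m$den[i, j])
           })
         }))
  }
  x <- list(goal = h$goal)
  if (!is.null(h$criteria_matrix)) {
    x$criteria_matrix <- jm_to_list(h$criteria_matrix)
  } else {
    x$criterion_weights <- as.list(h$criterion_weights)
  }
  x$alternatives <- lapply(h$alternative_matrices, jm_to_list)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else yaml::read_yaml(path)
  jm_from_list <- function(l) {
    judgment_matrix(l$entries, labels = unlist(l$labels))
  }
  alts <- lapply(x$alternatives, jm_from_list)
  cm <- if (!is.null(x$criteria_matrix)) jm_from_list(x$criteria_matrix) else NULL
  cw <- if (!is.null(x$criterion_weights)) unlist(x$criterion_weights) else NULL
  hierarchy(x$goal, alternative_matrices = alts, criteria_matrix = cm,
            criterion_weights = cw)
}

#' Export an AHP fit as a report
#'
#' @param fit An [ahp()] object.
#' @param path Output path (`.json` for JSON, anything else plain text);
#'   values at 4 decimal places.
#' @return `path`, invisibly.
#' @export
write_ahp_report <- function(fit, path) {
  stopifnot(inherits(fit, "ahp"))
  if (grepl("\\.json$", path)) {
    x <- list(goal = fit$goal,
              method = fit$method,
              combination_weights = as.list(round(fit$combination_weights, 4)),
              ranking = as.character(fit$ranking),
              combined_ci = round(fit$combined_ci, 4),
              combined_cr = round(fit$combined_cr, 4),
              acceptable = fit$acceptable,
              criterion_weights = as.list(round(fit$criterion_weights, 4)),
              criterion_ranking = as.character(fit$criterion_ranking))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    txt <- utils::capture.output(summary(fit))
    writeLines(txt, path)
  }
  invisible(path)
}
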