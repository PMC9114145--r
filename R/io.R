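#' Read and write muscle parameter tables
#'
#' The muscle table is a plain CSV with one row per MTU and the columns
#' documented in \code{\link{default_muscles}}.  A copy of the default
#' table ships with the package (\code{system.file("extdata",
#' "muscles_default.csv", package = "flexgait")}).
#'
#' @param path file path
#' @return an \code{fg_muscles} table
#' @export
read_muscle_table <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "leg", "Fmax", "lopt", "lslack", "vmax", "w", "fvN",
              "fvK", "epsref", "tauA", "ndof", "dof1", "r1", "thmax1",
              "thref1", "sgn1", "dof2", "r2", "thmax2", "thref2", "sgn2")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    stop("muscle table lacks columns: ", paste(missing, collapse = ", "))
  }
  m$leg <- as.integer(m$leg)
  m$ndof <- as.integer(m$ndof)
  m$dof1 <- as.integer(m$dof1)
  m$dof2 <- as.integer(m$dof2)
  rownames(m) <- m$name
  stopifnot(all(m$Fmax > 0), all(m$tauA > 0), all(m$lopt > 0))
  class(m) <- c("fg_muscles", "data.frame")
  m
}

#' @rdname read_muscle_table
#' @param muscles an \code{fg_muscles} table
#' @export
write_muscle_table <- function(muscles, path) {
  utils::write.csv(as.data.frame(muscles), path, row.names = FALSE)
  invisible(path)
}

#' Save / load the free controller parameters as JSON
#'
#' Stores the named 55-parameter vector (see
#' \code{\link{params_to_vector}}), so tuned controllers can be exchanged
#' as plain text.
#'
#' @param model an \code{fg_model}
#' @param path file path
#' @export
write_params_json <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON parameter files")
  }
  jsonlite::write_json(as.list(params_to_vector(model)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @param base model supplying the fixed structure
#' @export
read_params_json <- function(path, base = fg_model()) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON parameter files")
  }
  v <- unlist(jsonlite::read_json(path))
  vector_to_params(base, v)
}

#' Export a walking trajectory log as CSV
#'
#' One row per logged control step: time, the 14 generalized coordinates
#' and velocities, and the per-foot ground reaction force components.
#'
#' @param walk an \code{fg_walk} object
#' @param path file path
#' @export
write_walk_csv <- function(walk, path) {
  df <- data.frame(t = walk$t, walk$q, walk$qd, walk$grf,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
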