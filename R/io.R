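#' Read and write degree inputs
#'
#' Degree sequences are plain text, one nonnegative integer per line;
#' lines starting with `#` are comments and blank lines are skipped.
#' Degree distributions are two-column CSV files with header `k,p`.
#'
#' @param path File path.
#' @param degrees Integer degree sequence.
#' @param dist A [degree_distribution()].
#' @param comment Optional comment line(s) written atop the sequence.
#' @return `read_degree_sequence()` an integer vector;
#'   `read_degree_distribution()` a [degree_distribution()]; the writers
#'   return `path` invisibly.
#' @name degree_io
NULL

#' @rdname degree_io
#' @export
read_degree_sequence <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no degrees found in file", call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (any(is.na(vals)) || any(abs(vals - round(vals)) > 0) || any(vals < 0)) {
    stop("degree sequence file must contain nonnegative integers only",
      call. = FALSE
    )
  }
  as.integer(vals)
}

#' @rdname degree_io
#' @export
write_degree_sequence <- function(degrees, path, comment = NULL) {
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  writeLines(c(lines, format(degrees, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' @rdname degree_io
#' @export
read_degree_distribution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("k", "p") %in% names(df))) {
    stop("distribution file must have header `k,p`", call. = FALSE)
  }
  degree_distribution(df$k, df$p)
}

#' @rdname degree_io
#' @export
write_degree_distribution <- function(dist, path) {
  writeLines(
    c("k,p", paste(fmt12(dist$k), fmt12(dist$p), sep = ",")),
    path
  )
  invisible(path)
}

# 12 significant digits, locale-independent; deterministic output
fmt12 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

fmt_bool <- function(x) {
  ifelse(is.na(x), "NA", ifelse(x, "true", "false"))
}

#' Export model constants as JSON
#'
#' Writes the moment triple and all derived constants as a flat JSON
#' object with keys `k1, k2, k3, alpha, beta, kbar, delta_c, sigma,
#' lambda, mu`.
#'
#' @param constants A [model_constants()] row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_constants_json <- function(constants, path) {
  cc <- constants_row(constants)
  jsonlite::write_json(
    list(
      k1 = cc$k1, k2 = cc$k2, k3 = cc$k3,
      alpha = cc$alpha, beta = cc$beta, kbar = cc$kbar,
      delta_c = cc$delta_c, sigma = cc$sigma,
      lambda = cc$lambda, mu = cc$mu
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Export results as CSV
#'
#' Deterministic CSV writers (12 significant digits, `.` decimal
#' separator, no locale dependence) for the toolkit's result tables:
#'
#' * trajectories: header `T,v,w,x,y,z`;
#' * bifurcation diagrams: header
#'   `delta,dfe_stable,endemic_exists,w_exact,w_near,w_far,residP,residQ`;
#' * sensitivity grids: header
#'   `k1,k2,k3,regime,delta,feasible,d_k1,d_k2,d_k3`.
#'
#' @param traj,bd,grid The respective result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name result_io
NULL

#' @rdname result_io
#' @export
write_trajectory_csv <- function(traj, path) {
  writeLines(
    c(
      "T,v,w,x,y,z",
      paste(fmt12(traj$T), fmt12(traj$v), fmt12(traj$w), fmt12(traj$x),
        fmt12(traj$y), fmt12(traj$z),
        sep = ","
      )
    ),
    path
  )
  invisible(path)
}

#' @rdname result_io
#' @export
write_bifurcation_csv <- function(bd, path) {
  writeLines(
    c(
      "delta,dfe_stable,endemic_exists,w_exact,w_near,w_far,residP,residQ",
      paste(fmt12(bd$delta), fmt_bool(bd$dfe_stable),
        fmt_bool(bd$endemic_exists), fmt12(bd$w_exact), fmt12(bd$w_near),
        fmt12(bd$w_far), fmt12(bd$resid_P), fmt12(bd$resid_Q),
        sep = ","
      )
    ),
    path
  )
  invisible(path)
}

#' @rdname result_io
#' @export
write_sensitivity_csv <- function(grid, path) {
  writeLines(
    c(
      "k1,k2,k3,regime,delta,feasible,d_k1,d_k2,d_k3",
      paste(fmt12(grid$k1), fmt12(grid$k2), fmt12(grid$k3), grid$regime,
        fmt12(grid$delta), fmt_bool(grid$feasible), fmt12(grid$d_k1),
        fmt12(grid$d_k2), fmt12(grid$d_k3),
        sep = ","
      )
    ),
    path
  )
  invisible(path)
}

#' Export a bifurcation summary as JSON
#'
#' Writes the [glance.scpw_bifurcation()] summary (threshold, endemic
#' branch extent, worst-case approximation errors on their sub-ranges).
#'
#' @param bd A [bifurcation_diagram()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_summary_json <- function(bd, path) {
  g <- glance(bd)
  jsonlite::write_json(as.list(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
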