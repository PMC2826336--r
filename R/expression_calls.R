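#' Construct a time-course log-ratio matrix with per-cell p-values
#'
#' Container for a two-channel expression time course: one log2(treated /
#' control) ratio and one p-value per gene and time point.
#'
#' @param ratio numeric matrix, genes x time points, of log2 ratios; row
#'   names are gene ids.
#' @param p numeric matrix of the same shape with per-cell p-values in
#'   `[0, 1]`.
#' @param timepoints strictly increasing numeric vector of sampling hours.
#' @return object of class `time_course_matrix`.
#' @export
time_course_matrix <- function(ratio, p, timepoints) {
  ratio <- as.matrix(ratio)
  p <- as.matrix(p)
  timepoints <- as.numeric(timepoints)
  if (is.null(rownames(ratio)) || anyNA(rownames(ratio)) ||
      any(rownames(ratio) == "")) {
    stop("ratio matrix must have complete gene ids as row names")
  }
  if (!identical(dim(ratio), dim(p))) stop("ratio and p dimensions differ")
  if (ncol(ratio) != length(timepoints)) {
    stop("number of columns must equal number of time points")
  }
  if (any(diff(timepoints) <= 0)) stop("time points must be strictly increasing")
  if (anyNA(ratio) || anyNA(p)) stop("missing values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  rownames(p) <- rownames(ratio)
  colnames(ratio) <- colnames(p) <- as.character(timepoints)
  structure(list(ratio = ratio, p = p, timepoints = timepoints),
            class = "time_course_matrix")
}

#' @export
print.time_course_matrix <- function(x, ...) {
  cat("time_course_matrix:", nrow(x$ratio), "genes x",
      length(x$timepoints), "time points (h):",
      paste(x$timepoints, collapse = ", "), "\n")
  invisible(x)
}

#' Calling configuration for induction / repression rules
#'
#' Defaults implement the calling rules of the chilling experiment: a time
#' point is induced when log2 ratio >= 1.8 at p < 0.05; an upregulated gene
#' needs at least two consecutive induced samples and no significantly
#' repressed sample; a downregulated gene needs one repressed sample and no
#' ratio at or above the up threshold (regardless of that ratio's p-value).
#'
#' @param up_threshold log2-units induction threshold (default 1.8).
#' @param down_threshold log2-units repression threshold (default -1.8).
#' @param alpha per-time-point significance level (default 0.05).
#' @param min_consecutive_up consecutive induced samples required for the up
#'   call (default 2; use 1 for the oxidative-mimic series).
#' @param require_never_down if TRUE (default) the up call excludes genes
#'   with any significantly repressed time point.
#' @param down_excludes_by_ratio_only if TRUE (default) the down call's
#'   exclusion of genes reaching the up threshold ignores p-values.
#' @param per_timepoint_alpha if TRUE (default) the p < alpha filter applies
#'   at every induced time point individually.
#' @param phase_boundaries two increasing hours splitting phases 1/2/3 with
#'   inclusive upper bounds (default `c(6, 24)`).
#' @return object of class `call_config`.
#' @export
call_config <- function(up_threshold = 1.8, down_threshold = -1.8,
                        alpha = 0.05, min_consecutive_up = 2L,
                        require_never_down = TRUE,
                        down_excludes_by_ratio_only = TRUE,
                        per_timepoint_alpha = TRUE,
                        phase_boundaries = c(6, 24)) {
  if (!(up_threshold > 0 && down_threshold < 0)) {
    stop("need up_threshold > 0 > down_threshold")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (min_consecutive_up < 1) stop("min_consecutive_up must be >= 1")
  if (length(phase_boundaries) != 2 || diff(phase_boundaries) <= 0) {
    stop("phase_boundaries must be two increasing hours")
  }
  structure(list(up_threshold = up_threshold, down_threshold = down_threshold,
                 alpha = alpha, min_consecutive_up = as.integer(min_consecutive_up),
                 require_never_down = require_never_down,
                 down_excludes_by_ratio_only = down_excludes_by_ratio_only,
                 per_timepoint_alpha = per_timepoint_alpha,
                 phase_boundaries = phase_boundaries),
            class = "call_config")
}

# Logical matrix of induced cells under the per-time-point rule.
induced_matrix <- function(matrix, config) {
  ind <- matrix$ratio >= config$up_threshold
  if (config$per_timepoint_alpha) ind <- ind & (matrix$p < config$alpha)
  ind
}

# Longest run of TRUE in a logical vector.
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Call upregulated genes from a time course
#'
#' A gene is called up when it has at least `min_consecutive_up` consecutive
#' induced samples (ratio >= `up_threshold` with p < `alpha`) and, when
#' `require_never_down`, no sample with ratio <= `down_threshold` at
#' p < `alpha`.
#'
#' @param matrix a [time_course_matrix()].
#' @param config a [call_config()].
#' @return data.frame of calls with columns `gene_id`, `status`, `phase`,
#'   `first_induced`, `waves` (serialized `start-end;start-end`),
#'   `interrupted`, and a list column `induced` of induced hours.
#' @export
call_upregulated <- function(matrix, config = call_config()) {
  if (length(matrix$timepoints) < config$min_consecutive_up) {
    stop("fewer time points than min_consecutive_up")
  }
  ind <- induced_matrix(matrix, config)
  runs <- apply(ind, 1L, longest_true_run)
  keep <- runs >= config$min_consecutive_up
  if (config$require_never_down) {
    down <- (matrix$ratio <= config$down_threshold) & (matrix$p < config$alpha)
    keep <- keep & !apply(down, 1L, any)
  }
  build_calls(matrix, ind, keep, status = "up", config = config)
}

#' Call downregulated genes from a time course
#'
#' A gene is called down when at least one sample has ratio <=
#' `down_threshold` at p < `alpha` and no sample reaches the up threshold
#' (by default the exclusion looks at the ratio alone, ignoring its
#' p-value).
#'
#' @inheritParams call_upregulated
#' @return data.frame of calls (`status = "down"`, `phase = NA`).
#' @export
call_downregulated <- function(matrix, config = call_config()) {
  rep_cells <- (matrix$ratio <= config$down_threshold) & (matrix$p < config$alpha)
  keep <- apply(rep_cells, 1L, any)
  up_cells <- matrix$ratio >= config$up_threshold
  if (!config$down_excludes_by_ratio_only) {
    up_cells <- up_cells & (matrix$p < config$alpha)
  }
  keep <- keep & !apply(up_cells, 1L, any)
  build_calls(matrix, rep_cells, keep, status = "down", config = config)
}

#' Call oxidative-mimic responsive genes
#'
#' Single-time-point variant of [call_upregulated()] used for the short
#' H2O2 series: one induced sample suffices and the never-down guard is
#' off.
#'
#' @inheritParams call_upregulated
#' @return character vector of responsive gene ids.
#' @export
call_h2o2_responsive <- function(matrix, config = call_config()) {
  cfg <- config
  cfg$min_consecutive_up <- 1L
  cfg$require_never_down <- FALSE
  call_upregulated(matrix, cfg)$gene_id
}

build_calls <- function(matrix, cells, keep, status, config) {
  genes <- rownames(matrix$ratio)[keep]
  induced <- lapply(which(keep), function(i) matrix$timepoints[cells[i, ]])
  names(induced) <- genes
  waves <- lapply(induced, segment_waves, timepoints = matrix$timepoints)
  phase <- if (status == "up") {
    vapply(induced, function(tp) assign_phase(min(tp), config), integer(1))
  } else {
    rep(NA_integer_, length(genes))
  }
  df <- data.frame(
    gene_id = genes,
    status = rep(status, length(genes)),
    phase = phase,
    first_induced = vapply(induced, function(tp) {
      if (length(tp)) min(tp) else NA_real_
    }, numeric(1)),
    waves = vapply(waves, function(w) {
      paste(sprintf("%g-%g", w$start, w$end), collapse = ";")
    }, character(1)),
    interrupted = vapply(waves, function(w) nrow(w) > 1L, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$induced <- unname(induced)
  df
}

#' Segment induced time points into induction waves
#'
#' A wave is a maximal run of consecutive sampled time points at which the
#' gene is induced; "consecutive" means adjacent in the sampling order, not
#' adjacent clock hours. Duration is last minus first hour of the wave.
#'
#' @param induced numeric vector of induced hours (subset of `timepoints`).
#' @param timepoints the full sampled time grid.
#' @return data.frame with columns `start`, `end`, `duration` (hours); zero
#'   rows when nothing is induced.
#' @export
segment_waves <- function(induced, timepoints) {
  if (!all(induced %in% timepoints)) {
    stop("induced hours must be a subset of the time grid")
  }
  idx <- sort(match(induced, timepoints))
  if (length(idx) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  }
  grp <- cumsum(c(1L, diff(idx) != 1L))
  starts <- tapply(idx, grp, min)
  ends <- tapply(idx, grp, max)
  data.frame(start = timepoints[starts], end = timepoints[ends],
             duration = timepoints[ends] - timepoints[starts],
             row.names = NULL)
}

#' Assign a response phase from the earliest induced hour
#'
#' Phase 1 ("early rapid") begins within the first boundary (default 6 h,
#' inclusive), phase 2 ("early slow") between the boundaries (default 6-24 h,
#' upper bound inclusive), phase 3 ("late") after the second boundary.
#'
#' @param first_hour earliest induced hour.
#' @param config a [call_config()] supplying `phase_boundaries`.
#' @return integer phase in `{1, 2, 3}`.
#' @export
assign_phase <- function(first_hour, config = call_config()) {
  if (length(first_hour) != 1L || is.na(first_hour)) {
    stop("phase is undefined without an induced time point")
  }
  b <- config$phase_boundaries
  if (first_hour <= b[1]) 1L else if (first_hour <= b[2]) 2L else 3L
}

#' Partition two gene sets into intersection and set differences
#'
#' @param setA,setB character vectors of gene ids.
#' @return list with `both`, `only_a`, `only_b` and a named `counts` vector.
#' @export
overlap_sets <- function(setA, setB) {
  setA <- unique(setA)
  setB <- unique(setB)
  both <- intersect(setA, setB)
  only_a <- setdiff(setA, setB)
  only_b <- setdiff(setB, setA)
  list(both = both, only_a = only_a, only_b = only_b,
       counts = c(a = length(setA), b = length(setB), both = length(both),
                  only_a = length(only_a), only_b = length(only_b)))
}
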