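#' Specify a stepped wedge design from its sequence taxonomy
#'
#' A stepped wedge cluster randomized trial (SW-CRT) is described, one
#' treatment sequence at a time, by the calendar periods over which data are
#' collected under each condition: `b0[s]..b1[s]` are the first and last
#' calendar periods of data collection in the control condition and
#' `q0[s]..q1[s]` the first and last under intervention. Calendar periods
#' between `b1[s]` and `q0[s]` are implementation periods with no data
#' collection; periods before `b0[s]` or after `q1[s]` correspond to staggered
#' entry or early termination. A complete design has `b0 = 1`, `q1 = J` and
#' `q0 = b1 + 1` in every sequence.
#'
#' @param n_periods Total number of calendar periods `J` in the trial.
#' @param b0,b1 Integer vectors (one entry per sequence): first/last calendar
#'   period of data collection in the control condition.
#' @param q0,q1 Integer vectors: first/last calendar period of data collection
#'   in the intervention condition.
#' @param clusters_per_sequence Number of clusters `m_s` randomized to each
#'   sequence; recycled to the number of sequences.
#' @param cluster_period_size Number of individuals `N` observed per
#'   cluster-period (constant across cluster-periods).
#' @param design_type `"cross-sectional"` (new individuals each period) or
#'   `"closed-cohort"` (the same individuals followed across periods).
#'
#' @return An object of class `sw_design`.
#' @examples
#' # the 2-sequence, 4-period incomplete design with one implementation
#' # period per sequence
#' d <- sw_design(4, b0 = c(1, 1), b1 = c(1, 2), q0 = c(3, 4), q1 = c(4, 4))
#' dp_cm(d)
#' @seealso [connect_home_design()], [hemming_design()], [dp_cm()]
#' @export
sw_design <- function(n_periods, b0, b1, q0, q1,
                      clusters_per_sequence = 1L,
                      cluster_period_size = 1L,
                      design_type = c("cross-sectional", "closed-cohort")) {
  design_type <- match.arg(design_type)
  S <- length(b0)
  stopifnot(length(b1) == S, length(q0) == S, length(q1) == S, S >= 1)
  J <- as.integer(n_periods)
  m_s <- as.integer(rep_len(clusters_per_sequence, S))
  N <- as.integer(cluster_period_size)
  if (N < 1) abort("`cluster_period_size` must be a positive integer.")
  if (any(m_s < 1)) abort("`clusters_per_sequence` entries must be positive.")
  for (s in seq_len(S)) {
    ok <- 1 <= b0[s] && b0[s] <= b1[s] && b1[s] < q0[s] &&
      q0[s] <= q1[s] && q1[s] <= J
    if (!ok) {
      abort(sprintf(
        "Invalid taxonomy in sequence %d: need 1 <= b0 <= b1 < q0 <= q1 <= J, got (%d, %d, %d, %d) with J = %d.",
        s, b0[s], b1[s], q0[s], q1[s], J
      ))
    }
  }
  c_s <- as.integer(q0 - b1 - 1L)
  structure(
    list(
      n_sequences = S, n_periods = J,
      b0 = as.integer(b0), b1 = as.integer(b1),
      q0 = as.integer(q0), q1 = as.integer(q1),
      implementation_periods = c_s,
      clusters_per_sequence = m_s,
      cluster_period_size = N,
      design_type = design_type
    ),
    class = "sw_design"
  )
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf(
    "Stepped wedge design: %d sequences, %d periods, %d clusters, N = %d per cluster-period (%s)\n",
    x$n_sequences, x$n_periods, n_clusters(x), x$cluster_period_size,
    x$design_type
  ))
  dp <- dp_cm(x)$dp
  sym <- ifelse(is.na(dp), ".", as.character(dp))
  for (s in seq_len(nrow(sym))) {
    cat(sprintf("  s%d [m=%d]: %s\n", s, x$clusters_per_sequence[s],
                paste(sym[s, ], collapse = "")))
  }
  invisible(x)
}

#' Total number of clusters in a design
#' @param design An [sw_design()].
#' @return Integer `I = sum(m_s)`.
#' @export
n_clusters <- function(design) sum(design$clusters_per_sequence)

#' Calendar periods with data collection for one sequence
#' @param design An [sw_design()].
#' @param s Sequence index.
#' @return Increasing integer vector of observed calendar periods.
#' @export
observed_periods <- function(design, s) {
  c(design$b0[s]:design$b1[s], design$q0[s]:design$q1[s])
}

#' Design pattern and completeness matrices
#'
#' The design pattern (DP) matrix is the sequences-by-periods treatment grid
#' with entries 0 (control), 1 (intervention) and `NA` (no data collection);
#' the completeness matrix (CM) is its 0/1 observed-data indicator. Together
#' they fully encode an incomplete stepped wedge layout.
#'
#' @param design An [sw_design()].
#' @return A list with integer matrices `dp` (`NA` for no-data cells) and `cm`.
#' @export
dp_cm <- function(design) {
  S <- design$n_sequences; J <- design$n_periods
  dp <- matrix(NA_integer_, S, J)
  for (s in seq_len(S)) {
    dp[s, design$b0[s]:design$b1[s]] <- 0L
    dp[s, design$q0[s]:design$q1[s]] <- 1L
  }
  cm <- matrix(as.integer(!is.na(dp)), S, J)
  list(dp = dp, cm = cm)
}

#' Incidence matrix of one completeness-matrix row
#'
#' The incidence matrix `K_s` selects observed-period rows from any
#' `J`-row matrix: `K_s %*% M` keeps exactly the rows of `M` at observed
#' calendar periods, in calendar order. It satisfies `K_s %*% t(K_s) ==
#' diag(nrow(K_s))`.
#'
#' @param cm_row Binary vector of length `J` (1 = data collected).
#' @return A 0/1 matrix with one row per observed period and `J` columns.
#' @export
incidence_matrix <- function(cm_row) {
  obs <- which(cm_row == 1)
  if (length(obs) == 0) abort("Sequence is never observed: completeness row is all zero.")
  K <- matrix(0L, length(obs), length(cm_row))
  K[cbind(seq_along(obs), obs)] <- 1L
  K
}

#' The Connect-Home trial design
#'
#' Reconstruction of the incomplete, cross-sectional stepped wedge design of
#' the Connect-Home trial: six skilled nursing facilities (sequences), 22
#' monthly periods, two implementation periods per sequence and staggered
#' entry/termination. Sequence `s` collects control data in calendar periods
#' `s..(2s+3)`, has implementation periods `(2s+4)..(2s+5)` and collects
#' intervention data in `(2s+6)..(s+16)`, so every sequence contributes 15
#' observed cluster-periods and the trial enrolls 360 individuals in total.
#' With `clusters = 6` there is one cluster per sequence and 4 individuals
#' per cluster-period; with `clusters = 12`, two clusters per sequence and 2
#' individuals per cluster-period (same total enrollment).
#'
#' @param clusters Total number of clusters: 6 or 12.
#' @param cluster_period_size Override the default cluster-period size
#'   (4 for 6 clusters, 2 for 12).
#' @param design_type Passed to [sw_design()]; the trial itself is
#'   cross-sectional, the closed-cohort variant is used with cohort
#'   correlation structures.
#' @return An [sw_design()].
#' @examples
#' connect_home_design(6)
#' @export
connect_home_design <- function(clusters = 6,
                                cluster_period_size = NULL,
                                design_type = "cross-sectional") {
  if (!clusters %in% c(6L, 12L)) {
    abort("`clusters` must be 6 or 12 (one or two clusters per sequence).")
  }
  s <- 1:6
  N <- if (is.null(cluster_period_size)) {
    if (clusters == 6) 4L else 2L
  } else {
    as.integer(cluster_period_size)
  }
  sw_design(
    n_periods = 22,
    b0 = s, b1 = 2 * s + 3, q0 = 2 * s + 6, q1 = s + 16,
    clusters_per_sequence = clusters / 6,
    cluster_period_size = N,
    design_type = design_type
  )
}

#' The two-sequence, four-period incomplete design
#'
#' A minimal incomplete stepped wedge layout with two sequences, four periods
#' and one implementation period per sequence (period 2 for sequence 1,
#' period 3 for sequence 2), specified by taxonomies (1, 1, 3, 4) and
#' (1, 2, 4, 4). Useful as a worked example and for exact checks of the
#' design-matrix algebra.
#'
#' @inheritParams connect_home_design
#' @param clusters_per_sequence Clusters per sequence.
#' @return An [sw_design()].
#' @export
hemming_design <- function(cluster_period_size = 1,
                           clusters_per_sequence = 1,
                           design_type = "cross-sectional") {
  sw_design(
    n_periods = 4,
    b0 = c(1, 1), b1 = c(1, 2), q0 = c(3, 4), q1 = c(4, 4),
    clusters_per_sequence = clusters_per_sequence,
    cluster_period_size = cluster_period_size,
    design_type = design_type
  )
}

# ---- design grid file I/O ---------------------------------------------------

#' Read / write a stepped wedge design as a text grid
#'
#' The grid dialect is one line per sequence with symbols `0` (control),
#' `1` (intervention) and `.` (no data collection); whitespace is ignored and
#' lines starting with `#` are comments. Companion scalars
#' (`clusters_per_sequence`, `cluster_period_size`, `design_type`) live in a
#' YAML sidecar `<path>.yml`, written by `write_sw_design()` and read back by
#' `read_sw_design()` when present.
#'
#' @param path Path of the grid file.
#' @param design An [sw_design()].
#' @return `read_sw_design()` returns an [sw_design()]; `write_sw_design()`
#'   returns `path` invisibly.
#' @export
read_sw_design <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort("Design grid file contains no sequence rows.")
  rows <- lapply(seq_along(lines), function(i) {
    chars <- strsplit(gsub("[[:space:]]", "", lines[i]), "")[[1]]
    bad <- setdiff(unique(chars), c("0", "1", "."))
    if (length(bad) > 0) {
      abort(sprintf("Invalid symbol '%s' in design grid row %d.", bad[1], i))
    }
    chars
  })
  J <- length(rows[[1]])
  if (any(lengths(rows) != J)) abort("Design grid rows have unequal lengths.")
  tax <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    z <- which(r == "0"); o <- which(r == "1")
    if (length(z) == 0 || length(o) == 0) {
      abort(sprintf("Row %d needs at least one control and one intervention period.", i))
    }
    if (any(diff(z) != 1) || any(diff(o) != 1)) {
      abort(sprintf("Row %d: control/intervention periods must be contiguous.", i))
    }
    if (max(z) >= min(o)) {
      abort(sprintf("Row %d: treatment must be non-decreasing (0s before 1s).", i))
    }
    c(b0 = min(z), b1 = max(z), q0 = min(o), q1 = max(o))
  })
  tax <- do.call(rbind, tax)
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  sw_design(
    n_periods = J,
    b0 = tax[, "b0"], b1 = tax[, "b1"], q0 = tax[, "q0"], q1 = tax[, "q1"],
    clusters_per_sequence = meta$clusters_per_sequence %||% 1L,
    cluster_period_size = meta$cluster_period_size %||% 1L,
    design_type = meta$design_type %||% "cross-sectional"
  )
}

#' @rdname read_sw_design
#' @export
write_sw_design <- function(design, path) {
  dp <- dp_cm(design)$dp
  sym <- ifelse(is.na(dp), ".", as.character(dp))
  writeLines(apply(sym, 1, paste, collapse = ""), path)
  yaml::write_yaml(
    list(
      clusters_per_sequence = design$clusters_per_sequence,
      cluster_period_size = design$cluster_period_size,
      design_type = design$design_type
    ),
    paste0(path, ".yml")
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
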