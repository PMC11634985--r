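# Simplified ROI-to-ROI resting-state connectivity contrast: bandpass the
# per-region time series, correlate region pairs, Fisher-z transform,
# paired pre/post t tests per edge with Benjamini-Hochberg FDR control,
# and association of edge changes with behavioral change.

#' ROI time-series container
#'
#' @param values Numeric `T x R` matrix: `T` timepoints (rows, >= 30) by
#'   `R` regions (columns, >= 2); no missing values.
#' @param tr Seconds per timepoint (repetition time).
#' @param subject Subject identifier.
#' @param phase `"PRE"` or `"POST"`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr, subject = "s1",
                           phase = c("PRE", "POST")) {
  phase <- match.arg(phase)
  values <- as.matrix(values)
  if (nrow(values) < 30) stop("need at least 30 timepoints", call. = FALSE)
  if (ncol(values) < 2) stop("need at least 2 regions", call. = FALSE)
  if (anyNA(values)) stop("missing values in time series", call. = FALSE)
  stopifnot(tr > 0)
  structure(list(values = values, tr = tr, subject = as.character(subject),
                 phase = phase),
            class = "roi_timeseries")
}

#' Zero-phase frequency-domain bandpass filter
#'
#' Per-column FFT filter retaining frequency components in
#' `[f_lo, f_hi]` Hz. The filter is zero-phase by construction (bins are
#' kept or zeroed, never phase-shifted). When `f_lo > 0` the DC component
#' is removed, so the output columns have mean ~0. The conventional
#' resting-state band 0.01-0.09 Hz is the default.
#'
#' @param ts A [roi_timeseries()].
#' @param f_lo,f_hi Band edges in Hz; `0 <= f_lo < f_hi <= 1/(2 tr)`.
#' @return A filtered `roi_timeseries`.
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.09) {
  nyq <- 1 / (2 * ts$tr)
  if (f_lo < 0 || f_hi <= f_lo || f_hi > nyq + 1e-12) {
    stop(structure(
      class = c("hwnav_domain_error", "error", "condition"),
      list(message = sprintf(
        "band [%g, %g] Hz invalid for Nyquist %g Hz", f_lo, f_hi, nyq),
        call = NULL)))
  }
  x <- ts$values
  n <- nrow(x)
  freq <- (seq_len(n) - 1L) / (n * ts$tr)
  freq <- pmin(freq, 1 / ts$tr - freq)  # fold to [0, Nyquist]
  keep <- freq >= f_lo - 1e-12 & freq <= f_hi + 1e-12
  filt <- apply(x, 2, function(col) {
    Re(stats::fft(stats::fft(col) * keep, inverse = TRUE)) / n
  })
  out <- ts
  out$values <- filt
  out
}

#' ROI-to-ROI Fisher-z connectivity matrix
#'
#' Pearson correlation of every region pair, Fisher z transformed
#' (`z = atanh(r)`, with `|r|` capped at `1 - 1e-12` so perfectly
#' correlated pairs stay finite). Edges involving a constant region are
#' `NA` and flagged.
#'
#' @param ts A [roi_timeseries()].
#' @return An object of class `connectivity_matrix`: `z` (symmetric
#'   `R x R`, diagonal `NA`), `subject`, `phase`, `undefined_edges`
#'   (logical matrix flagging constant-region edges).
#' @export
connectivity <- function(ts) {
  x <- ts$values
  sds <- apply(x, 2, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  r <- suppressWarnings(stats::cor(x))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- NA_real_
  undef <- outer(const, const, "|")
  diag(undef) <- FALSE
  structure(list(z = z, subject = ts$subject, phase = ts$phase,
                 undefined_edges = undef),
            class = "connectivity_matrix")
}

# unique upper-triangle edge index pairs of an R x R matrix
edge_pairs <- function(R) {
  idx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Paired pre/post contrast over all connectivity edges
#'
#' For every unique ROI pair, a two-sided paired t test on the Fisher-z
#' values (post - pre per subject), with Benjamini-Hochberg FDR control
#' over the `R(R-1)/2` edges. An edge is significant when its adjusted p
#' is at most `q`.
#'
#' @param pre,post Lists of [connectivity()] matrices, one per subject,
#'   with matching subject identifiers (>= 3 subjects).
#' @param q FDR level (default 0.05).
#' @return An object of class `edge_contrast`: data frame `edges` with
#'   columns `roi_i, roi_j, mean_delta_z, t, p, p_fdr, significant,
#'   direction`, plus matrices `t_matrix`, `p_fdr_matrix` and the logical
#'   `mask` (all symmetric).
#' @export
paired_edge_contrast <- function(pre, post, q = 0.05) {
  if (length(pre) != length(post) || length(pre) < 3) {
    stop(structure(
      class = c("hwnav_pairing_error", "error", "condition"),
      list(message = "need the same >= 3 subjects in both phases",
           call = NULL)))
  }
  pre_ids <- vapply(pre, function(cm) cm$subject, character(1))
  post_ids <- vapply(post, function(cm) cm$subject, character(1))
  if (!identical(sort(pre_ids), sort(post_ids))) {
    stop(structure(
      class = c("hwnav_pairing_error", "error", "condition"),
      list(message = "subject identifiers differ between phases",
           call = NULL)))
  }
  post <- post[match(pre_ids, post_ids)]
  R <- nrow(pre[[1]]$z)
  ep <- edge_pairs(R)
  n_sub <- length(pre)
  dz <- vapply(seq_len(n_sub), function(s) {
    post[[s]]$z[ep] - pre[[s]]$z[ep]
  }, numeric(nrow(ep)))
  dz <- matrix(dz, nrow = nrow(ep))
  mean_d <- rowMeans(dz)
  sd_d <- apply(dz, 1, stats::sd)
  tstat <- mean_d / (sd_d / sqrt(n_sub))
  tstat[sd_d < .Machine$double.eps] <- 0
  p <- 2 * stats::pt(-abs(tstat), n_sub - 1L)
  p_fdr <- stats::p.adjust(p, method = "BH")
  sig <- p_fdr <= q
  edges <- data.frame(
    roi_i = ep[, 1], roi_j = ep[, 2],
    mean_delta_z = mean_d, t = tstat, p = p, p_fdr = p_fdr,
    significant = sig,
    direction = ifelse(mean_d >= 0, "increase", "decrease"))
  sym <- function(v, fill = NA_real_) {
    mm <- matrix(fill, R, R)
    mm[ep] <- v
    mm[ep[, c(2, 1)]] <- v
    mm
  }
  structure(
    list(edges = edges, q = q, n_subjects = n_sub,
         t_matrix = sym(tstat), p_fdr_matrix = sym(p_fdr),
         mask = sym(sig, fill = FALSE) > 0),
    class = "edge_contrast")
}

#' @export
print.edge_contrast <- function(x, ...) {
  cat(sprintf("<edge_contrast> %d subjects, %d edges, %d significant at q = %g\n",
              x$n_subjects, nrow(x$edges), sum(x$edges$significant), x$q))
  invisible(x)
}

#' Write the edge table as CSV
#'
#' @param contrast An `edge_contrast`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_csv <- function(contrast, path) {
  utils::write.csv(contrast$edges, path, row.names = FALSE)
  invisible(path)
}

#' Associate connectivity change with behavioral change
#'
#' Spearman rank correlation between per-subject connectivity deltas on
#' one edge and per-subject behavioral score deltas.
#'
#' @param edge_deltas,behavior_deltas Numeric per-subject changes
#'   (equal lengths >= 3).
#' @return As [spearman()]: list with `rho`, `p_value`, `n`, `degenerate`.
#' @export
behavior_association <- function(edge_deltas, behavior_deltas) {
  spearman(edge_deltas, behavior_deltas)
}

#' Generate a paired synthetic ROI dataset with planted connectivity change
#'
#' Draws per-subject multivariate Gaussian time series: PRE from
#' `baseline_cov` and POST from `baseline_cov` with `delta_r` added to the
#' correlation of each planted edge. Both matrices must be positive
#' definite. With unit variances the covariance doubles as the correlation
#' matrix.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param n_rois Number of regions (default 10).
#' @param T Timepoints per scan (>= 30, default 300).
#' @param baseline_cov `R x R` baseline covariance; default compound
#'   symmetry with off-diagonal 0.1.
#' @param planted_edges Two-column matrix of `(i, j)` region pairs
#'   receiving the connectivity increase (default none).
#' @param delta_r Correlation increase on planted edges (default 0).
#' @param tr Seconds per timepoint (default 2).
#' @param seed Integer seed; generation is deterministic and leaves the
#'   caller's RNG untouched.
#' @return List with `pre` and `post` (lists of [roi_timeseries()], one
#'   per subject), `baseline_cov`, `post_cov`, `planted_edges`.
#' @export
synth_roi_dataset <- function(n_subjects = 17, n_rois = 10, T = 300,
                              baseline_cov = NULL, planted_edges = NULL,
                              delta_r = 0, tr = 2, seed = 1L) {
  stopifnot(T >= 30, n_rois >= 2, n_subjects >= 1)
  if (is.null(baseline_cov)) {
    baseline_cov <- matrix(0.1, n_rois, n_rois)
    diag(baseline_cov) <- 1
  }
  check_pd <- function(mat, name) {
    ok <- tryCatch({chol(mat); TRUE}, error = function(e) FALSE)
    if (!ok) {
      stop(structure(
        class = c("hwnav_generation_error", "error", "condition"),
        list(message = paste0(name, " is not positive definite"),
             call = NULL)))
    }
  }
  check_pd(baseline_cov, "baseline_cov")
  post_cov <- baseline_cov
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    for (k in seq_len(nrow(planted_edges))) {
      i <- planted_edges[k, 1]; j <- planted_edges[k, 2]
      post_cov[i, j] <- post_cov[i, j] + delta_r
      post_cov[j, i] <- post_cov[i, j]
    }
  }
  check_pd(post_cov, "post_cov (baseline with planted edges)")
  with_local_seed(seed, function() {
    draw <- function(sig, subject, phase) {
      roi_timeseries(MASS::mvrnorm(T, mu = rep(0, n_rois), Sigma = sig),
                     tr = tr, subject = subject, phase = phase)
    }
    ids <- sprintf("sub%02d", seq_len(n_subjects))
    pre <- lapply(ids, function(id) draw(baseline_cov, id, "PRE"))
    post <- lapply(ids, function(id) draw(post_cov, id, "POST"))
    list(pre = pre, post = post, baseline_cov = baseline_cov,
         post_cov = post_cov, planted_edges = planted_edges)
  })
}

#' Read ROI time-series matrices via a manifest
#'
#' The manifest CSV has columns `subject, phase, path, tr`; each `path`
#' points to a delimited `T x R` matrix (no header) relative to the
#' manifest's directory (absolute paths are honored).
#'
#' @param manifest_path Manifest CSV path.
#' @return List with `pre` and `post` lists of [roi_timeseries()].
#' @export
read_roi_manifest <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject", "phase", "path", "tr")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  load_one <- function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    vals <- as.matrix(utils::read.table(p))
    roi_timeseries(vals, tr = man$tr[i], subject = man$subject[i],
                   phase = man$phase[i])
  }
  all_ts <- lapply(seq_len(nrow(man)), load_one)
  phases <- toupper(man$phase)
  list(pre = all_ts[phases == "PRE"], post = all_ts[phases == "POST"])
}
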