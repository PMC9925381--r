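#' Configuration for the synthetic sortChIC generator
#'
#' Bundles and validates the parameters of the multinomial cut-count
#' simulator: the number of genomic regions and cell types, per-type cell
#' counts, the log-normal sequencing-depth law, the fraction of regions
#' carrying planted cell-type differences and their fold changes, and an
#' optional per-plate batch effect in log-profile space.
#'
#' @param n_region Number of genomic regions (>= 1).
#' @param n_type Number of cell types (>= 1). Type 1 is the reference.
#' @param n_cell_per_type Cells per type; scalar or length-`n_type` vector
#'   (entries may be 0 to drop a type from the sample).
#' @param depth_median Median of the per-cell total cut count (log-normal).
#'   Default 3000, the sparsity regime of active-mark single-cell data.
#' @param depth_sigma Log-scale standard deviation of the depth law.
#' @param frac_dynamic Fraction of regions with planted type differences.
#' @param fold_spec Per-type multiplicative enrichment (> 0) applied at the
#'   planted regions before renormalisation; scalar or length `n_type`.
#'   The reference type's fold is forced to 1.
#' @param n_plate Number of plates cells are distributed over (round robin).
#' @param batch_sd Standard deviation of the per-plate region-wise shift in
#'   log-profile space (0 disables batch effects).
#' @param profile_mode `"planted"` (default): all types share a baseline
#'   profile, perturbed by `fold_spec` at the planted regions — the regime
#'   for differential testing. `"distinct"`: every type draws an
#'   independent profile, giving well-separated types — the regime for
#'   cell typing and deconvolution references.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_region, n_type, n_cell_per_type,
                       depth_median = 3000, depth_sigma = 0.5,
                       frac_dynamic = 0, fold_spec = 1,
                       n_plate = 1L, batch_sd = 0,
                       profile_mode = c("planted", "distinct"), seed = 1L) {
  profile_mode <- match.arg(profile_mode)
  if (n_region < 1 || n_type < 1) stop_config("n_region and n_type must be >= 1")
  n_cell_per_type <- rep_len(as.integer(n_cell_per_type), n_type)
  if (any(n_cell_per_type < 0)) stop_config("n_cell_per_type must be >= 0")
  if (frac_dynamic < 0 || frac_dynamic > 1) stop_config("frac_dynamic must be in [0,1]")
  if (length(fold_spec) != 1L && length(fold_spec) != n_type) {
    stop_config("fold_spec must have length 1 or n_type (%d), got %d",
                n_type, length(fold_spec))
  }
  fold_spec <- rep_len(as.numeric(fold_spec), n_type)
  if (any(fold_spec <= 0)) stop_config("fold_spec entries must be > 0")
  fold_spec[1L] <- 1
  if (depth_median < 1) stop_config("depth_median must be >= 1")
  if (batch_sd < 0) stop_config("batch_sd must be >= 0")
  structure(list(
    n_region = as.integer(n_region), n_type = as.integer(n_type),
    n_cell_per_type = n_cell_per_type,
    depth_median = depth_median, depth_sigma = depth_sigma,
    frac_dynamic = frac_dynamic, fold_spec = fold_spec,
    n_plate = as.integer(n_plate), batch_sd = batch_sd,
    profile_mode = profile_mode, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate per-type multinomial cut profiles with planted dynamic regions
#'
#' Draws a baseline probability profile over regions, marks a
#' `frac_dynamic` subset of regions as dynamic, multiplies the baseline at
#' those regions by each type's fold, and renormalises. Non-dynamic regions
#' share the baseline across all types.
#'
#' @param cfg A [sim_config()].
#' @return A list with `type_profiles` (type x region, rows sum to 1),
#'   `baseline`, `dynamic_mask` (logical per region) and `log2fold`
#'   (type x region true log2 fold of pre-normalisation mass vs reference).
#' @export
simulate_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream(cfg$seed, 1L), {
    baseline <- rgamma(cfg$n_region, shape = 2, rate = 1) + 1e-6
    baseline <- baseline / sum(baseline)
    if (cfg$profile_mode == "distinct") {
      profiles <- matrix(rgamma(cfg$n_type * cfg$n_region, shape = 0.3) + 1e-9,
                         cfg$n_type, cfg$n_region)
      profiles <- profiles / rowSums(profiles)
      dynamic_mask <- rep(TRUE, cfg$n_region)
      log2fold <- log2(sweep(profiles, 2L, profiles[1L, ], "/"))
    } else {
      n_dyn <- round(cfg$frac_dynamic * cfg$n_region)
      dynamic_mask <- rep(FALSE, cfg$n_region)
      if (n_dyn > 0) dynamic_mask[sample.int(cfg$n_region, n_dyn)] <- TRUE
      profiles <- matrix(baseline, nrow = cfg$n_type, ncol = cfg$n_region,
                         byrow = TRUE)
      log2fold <- matrix(0, cfg$n_type, cfg$n_region)
      for (t in seq_len(cfg$n_type)) {
        profiles[t, dynamic_mask] <- baseline[dynamic_mask] * cfg$fold_spec[t]
        log2fold[t, dynamic_mask] <- log2(cfg$fold_spec[t])
        profiles[t, ] <- profiles[t, ] / sum(profiles[t, ])
      }
    }
    rownames(profiles) <- paste0("type", seq_len(cfg$n_type))
    colnames(profiles) <- paste0("region", seq_len(cfg$n_region))
    dimnames(log2fold) <- dimnames(profiles)
    list(type_profiles = profiles, baseline = baseline,
         dynamic_mask = dynamic_mask, log2fold = log2fold)
  })
}

#' Simulate single cells from type profiles
#'
#' Each cell draws a total depth from the log-normal depth law, then its
#' counts from a multinomial over regions with its type's profile. When
#' `batch_sd > 0` each plate perturbs the log profile region-wise by a
#' shared Gaussian shift before renormalisation, emulating plate effects
#' that survive depth normalisation.
#'
#' @param truth Output of [simulate_profiles()].
#' @param cfg The same [sim_config()].
#' @return A list with `counts` (sparse region x cell dgCMatrix),
#'   `cell_labels` (type per cell), `plate` (plate per cell) and `depth`.
#' @export
simulate_cells <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  labels <- rep(paste0("type", seq_len(cfg$n_type)), cfg$n_cell_per_type)
  n_cell <- length(labels)
  if (n_cell == 0L) stop_config("no cells requested")
  with_seed(substream(cfg$seed, 2L), {
    plate <- paste0("plate", (seq_len(n_cell) - 1L) %% cfg$n_plate + 1L)
    shift <- matrix(0, cfg$n_plate, cfg$n_region)
    if (cfg$batch_sd > 0) {
      shift <- matrix(rnorm(cfg$n_plate * cfg$n_region, sd = cfg$batch_sd),
                      cfg$n_plate, cfg$n_region)
    }
    depth <- pmax(1L, as.integer(round(rlnorm(
      n_cell, meanlog = log(cfg$depth_median), sdlog = cfg$depth_sigma))))
    type_idx <- match(labels, rownames(truth$type_profiles))
    plate_idx <- as.integer(sub("plate", "", plate))
    counts <- matrix(0L, cfg$n_region, n_cell)
    for (i in seq_len(n_cell)) {
      p <- truth$type_profiles[type_idx[i], ]
      if (cfg$batch_sd > 0) {
        p <- exp(log(p) + shift[plate_idx[i], ])
        p <- p / sum(p)
      }
      counts[, i] <- rmultinom(1L, depth[i], p)[, 1L]
    }
    dimnames(counts) <- list(colnames(truth$type_profiles),
                             sprintf("cell%04d", seq_len(n_cell)))
    list(counts = as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         cell_labels = setNames(labels, colnames(counts)),
         plate = setNames(plate, colnames(counts)),
         depth = setNames(depth, colnames(counts)))
  })
}

#' Simulate double-incubated cells from a two-multinomial mixture
#'
#' Each double-incubated cell pairs an active-mark cell type `c` with a
#' repressive-mark lineage `l`; its counts are drawn
#' Multinomial(N, w * p_c + (1 - w) * q_l), where `w` is the fraction of
#' the active-mark chemistry in the mix.
#'
#' @param p_profiles Matrix of active-mark cluster profiles (cluster x
#'   region, rows sum to 1).
#' @param q_profiles Matrix of repressive-mark lineage profiles on the same
#'   region registry.
#' @param pairing Two-column matrix or data.frame of (c, l) indices or row
#'   names, one row per simulated cell.
#' @param w Mixing fraction in \[0, 1\]; scalar or per-cell vector.
#' @param depth Total reads N per cell; scalar or per-cell vector.
#' @param seed Integer seed.
#' @return A list with `counts` (region x cell sparse matrix) and
#'   `pair_labels` (data.frame cell, c, l, w_true, depth).
#' @export
simulate_double_cells <- function(p_profiles, q_profiles, pairing, w,
                                  depth, seed = 1L) {
  if (ncol(p_profiles) != ncol(q_profiles)) {
    stop_config("p and q profiles must share one region registry")
  }
  pairing <- as.data.frame(pairing)
  n_cell <- nrow(pairing)
  w <- rep_len(w, n_cell)
  if (any(w < 0 | w > 1)) stop_config("w must lie in [0,1]")
  depth <- rep_len(as.integer(depth), n_cell)
  ci <- if (is.numeric(pairing[[1L]])) as.integer(pairing[[1L]]) else
    match(pairing[[1L]], rownames(p_profiles))
  li <- if (is.numeric(pairing[[2L]])) as.integer(pairing[[2L]]) else
    match(pairing[[2L]], rownames(q_profiles))
  if (anyNA(ci) || anyNA(li)) stop_config("pairing refers to unknown clusters")
  with_seed(seed, {
    counts <- matrix(0L, ncol(p_profiles), n_cell)
    for (i in seq_len(n_cell)) {
      mix <- w[i] * p_profiles[ci[i], ] + (1 - w[i]) * q_profiles[li[i], ]
      counts[, i] <- rmultinom(1L, depth[i], mix)[, 1L]
    }
    cells <- sprintf("dbl%04d", seq_len(n_cell))
    dimnames(counts) <- list(colnames(p_profiles), cells)
    list(counts = as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         pair_labels = data.frame(cell = cells, c = ci, l = li,
                                  w_true = w, depth = depth))
  })
}

#' Simulate a motif activity design with planted activities
#'
#' Builds a sparse nonnegative region x motif site-count matrix N (Poisson
#' site counts), a motif x cell activity matrix A in which a configurable
#' subset of motifs is active with cell-block structure and the rest are
#' exact-zero null rows, and the signal Y = N A + Gaussian noise.
#'
#' @param n_region,n_motif,n_cell Dimensions (all >= 1).
#' @param n_active Number of active motifs (rest are null); default 3.
#' @param activity_scale Scale of planted activities; default 1.
#' @param noise_sd Gaussian noise standard deviation (>= 0). The special
#'   value `NULL` sets it to 0.1 x sd(N A), the calibration used in the
#'   recovery experiments.
#' @param site_rate Poisson mean of site counts; default 0.5 (sparse).
#' @param n_block Number of cell blocks structuring the active motifs.
#' @param seed Integer seed.
#' @return List with `N` (region x motif), `signal` (region x cell),
#'   `activity_true` (motif x cell), `noise_sd` (the value used).
#' @export
simulate_motif_design <- function(n_region, n_motif, n_cell, n_active = 3,
                                  activity_scale = 1, noise_sd = NULL,
                                  site_rate = 0.5, n_block = 3, seed = 1L) {
  if (n_region < 1 || n_motif < 1 || n_cell < 1) stop_config("dims must be >= 1")
  if (!is.null(noise_sd) && noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (n_active > n_motif) stop_config("n_active exceeds n_motif")
  with_seed(seed, {
    N <- matrix(rpois(n_region * n_motif, site_rate), n_region, n_motif)
    dimnames(N) <- list(paste0("region", seq_len(n_region)),
                        paste0("motif", seq_len(n_motif)))
    A <- matrix(0, n_motif, n_cell,
                dimnames = list(colnames(N), paste0("cell", seq_len(n_cell))))
    block <- rep_len(seq_len(n_block), n_cell)
    for (m in seq_len(n_active)) {
      block_means <- rnorm(n_block, sd = activity_scale)
      A[m, ] <- block_means[block] + rnorm(n_cell, sd = 0.1 * activity_scale)
    }
    mean_signal <- N %*% A
    if (is.null(noise_sd)) noise_sd <- 0.1 * sd(mean_signal)
    signal <- mean_signal + matrix(rnorm(n_region * n_cell, sd = noise_sd),
                                   n_region, n_cell)
    list(N = N, signal = signal, activity_true = A, noise_sd = noise_sd,
         active_motifs = rownames(A)[seq_len(n_active)], cell_block = block)
  })
}

#' Simulate FACS marker triples along a differentiation trajectory
#'
#' Places cells at pseudotimes t in \[0, 1\], evaluates a trajectory
#' specification mapping t to mean (Sca1, cKit, Lin) levels, adds Gaussian
#' noise, and masks exactly `round(missing_frac * n_cell)` cells (chosen by
#' permutation, so the masked count is deterministic) by deleting one
#' randomly chosen marker each.
#'
#' @param n_cell Number of cells.
#' @param trajectory_spec Function mapping a pseudotime vector to an
#'   `n x 3` matrix of (Sca1, cKit, Lin) means.
#' @param missing_frac Fraction of cells with exactly one masked marker,
#'   in \[0, 1).
#' @param noise_sd Marker noise standard deviation.
#' @param seed Integer seed.
#' @return List with `facs` (data.frame cell, Sca1, cKit, Lin with NAs at
#'   masked entries), `facs_truth` (pre-masking values) and `t_true`.
#' @export
simulate_facs_trajectory <- function(n_cell, trajectory_spec,
                                     missing_frac = 0, noise_sd = 0,
                                     seed = 1L) {
  if (missing_frac < 0 || missing_frac >= 1) {
    stop_config("missing_frac must be in [0,1)")
  }
  with_seed(seed, {
    t_true <- sort(runif(n_cell))
    mu <- trajectory_spec(t_true)
    if (!is.matrix(mu) || ncol(mu) != 3L) {
      stop_config("trajectory_spec must return an n x 3 matrix")
    }
    vals <- mu + matrix(rnorm(3L * n_cell, sd = noise_sd), n_cell, 3L)
    colnames(vals) <- c("Sca1", "cKit", "Lin")
    truth <- as.data.frame(vals)
    truth$cell <- sprintf("cell%04d", seq_len(n_cell))
    facs <- truth
    n_mask <- round(missing_frac * n_cell)
    if (n_mask > 0) {
      masked_cells <- sample.int(n_cell, n_mask)
      which_marker <- sample.int(3L, n_mask, replace = TRUE)
      for (j in seq_len(n_mask)) {
        facs[masked_cells[j], which_marker[j]] <- NA_real_
      }
    }
    list(facs = facs[, c("cell", "Sca1", "cKit", "Lin")],
         facs_truth = truth[, c("cell", "Sca1", "cKit", "Lin")],
         t_true = t_true)
  })
}
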