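## Seeded synthetic cohort generator. Emulates the statistical structure the
## analysis assumes: log-normally distributed transcript abundances with
## additive group effects on the log scale, optional correlated gene blocks
## drawn through a Gaussian copula, compositional immune-cell percentages
## renormalized to a sampled total-immune fraction, and censored exponential
## survival times with group-dependent hazards.

#' Specification of one synthetic analyte
#'
#' @param name Analyte name.
#' @param kind `"gene_tpm"` or `"cell_percent"`.
#' @param log_mean Location on the natural-log scale (for cell analytes this
#'   is the log of the relative compositional weight).
#' @param log_sd Positive scale on the log scale.
#' @param group_effect Named numeric vector of additive log-scale shifts per
#'   outcome group (missing groups default to 0).
#' @param corr_block Optional block label; analytes sharing a label are
#'   drawn with a common within-block Spearman correlation.
#' @param block_rho Target Spearman correlation of the block (|rho| < 1).
#' @return Object of class `analyte_spec`.
#' @export
analyte_spec <- function(name, kind = c("gene_tpm", "cell_percent"),
                         log_mean = 0, log_sd = 1,
                         group_effect = c(long = 0, intermediate = 0, short = 0),
                         corr_block = NA_character_, block_rho = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(log_sd > 0)
  if (!is.na(block_rho) && abs(block_rho) >= 1) {
    stop("block_rho must satisfy |rho| < 1")
  }
  eff <- c(long = 0, intermediate = 0, short = 0)
  eff[names(group_effect)] <- group_effect
  structure(list(name = name, kind = kind, log_mean = log_mean,
                 log_sd = log_sd, group_effect = eff,
                 corr_block = corr_block, block_rho = block_rho),
            class = "analyte_spec")
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the design of the profiled ovarian cancer cohort: group
#' sizes 11 (long), 8 (short) and 7 (intermediate); exponential
#' progression hazards matching the group median PFS of 76, 6 and 24
#' months; censoring concentrated in the long group; and a total immune
#' infiltrate averaging about 17% of the sample.
#'
#' @param group_sizes Named integer vector (`long`, `short`,
#'   `intermediate`); a group may be 0 to omit it.
#' @param analytes List of [analyte_spec()] objects; defaults to the
#'   40-analyte panel shaped on the bundled reference table
#'   (see [panel_specs()]).
#' @param pfs_hazard,os_extra_hazard Named per-group exponential rates
#'   (1/months): the progression hazard, and the hazard of the
#'   post-progression interval added to obtain overall survival.
#' @param censor_prob Named per-group probability that a progression time
#'   is administratively censored.
#' @param horizon Follow-up horizon in months; times beyond it are censored
#'   at the horizon.
#' @param total_immune_mean,total_immune_sd Mean and SD (percent) of the
#'   per-sample total immune fraction to which cell subsets are
#'   renormalized.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(group_sizes = c(long = 11, short = 8, intermediate = 7),
                         analytes = panel_specs(),
                         pfs_hazard = c(long = log(2) / 76,
                                        intermediate = log(2) / 24,
                                        short = log(2) / 6),
                         os_extra_hazard = c(long = log(2) / 3,
                                             intermediate = log(2) / 27,
                                             short = log(2) / 10),
                         censor_prob = c(long = 0.8, intermediate = 0.15,
                                         short = 0),
                         horizon = 100,
                         total_immune_mean = 17,
                         total_immune_sd = 2.5,
                         seed = 1) {
  stopifnot(all(group_sizes >= 0), sum(group_sizes) > 0)
  stopifnot(all(censor_prob >= 0 & censor_prob <= 1))
  stopifnot(all(vapply(analytes, inherits, logical(1), "analyte_spec")))
  structure(list(group_sizes = group_sizes, analytes = analytes,
                 pfs_hazard = pfs_hazard, os_extra_hazard = os_extra_hazard,
                 censor_prob = censor_prob, horizon = horizon,
                 total_immune_mean = total_immune_mean,
                 total_immune_sd = total_immune_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Analyte specifications shaped on the bundled reference panel
#'
#' Builds one [analyte_spec()] per analyte of the bundled 40-analyte immune
#' panel. Gene log-means are centered between the logs of the published
#' long/short group medians, with the group effect splitting the difference
#' (intermediate sits at the center), so simulated group medians land near
#' the printed ones. Cell analytes get compositional weights proportional
#' to their published median percentages. The ICOS/CTLA4 pair is drawn as a
#' correlated block with Spearman rho 0.89, mirroring the strong observed
#' co-expression of these two costimulatory-family transcripts.
#'
#' @param log_sd Common log-scale SD (default 0.6).
#' @param effects Scale factor on the planted group effects; 0 gives a null
#'   panel with no group signal.
#' @return List of `analyte_spec` objects.
#' @export
panel_specs <- function(log_sd = 0.6, effects = 1) {
  ref <- wihri_reference("analytes")
  specs <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    ml <- max(ref$median_long[i], 0.05)
    ms <- max(ref$median_short[i], 0.05)
    center <- (log(ml) + log(ms)) / 2
    half <- (log(ml) - log(ms)) / 2 * effects
    blk <- if (ref$analyte[i] %in% c("ICOS", "CTLA4")) "icos_ctla4" else NA
    rho <- if (!is.na(blk)) 0.89 else NA_real_
    specs[[i]] <- analyte_spec(
      name = ref$analyte[i], kind = ref$kind[i],
      log_mean = center, log_sd = log_sd,
      group_effect = c(long = half, intermediate = 0, short = -half),
      corr_block = blk, block_rho = rho
    )
  }
  specs
}

#' Generate a synthetic cohort
#'
#' Draws an [cohort()] from a [synth_config()]. Gene TPM values are
#' log-normal: `exp(log_mean + group_effect + log_sd * Z)` with `Z` standard
#' normal; analytes sharing a correlation block are drawn from a Gaussian
#' copula whose latent correlation `2 sin(pi rho / 6)` yields the block's
#' target Spearman rho. Cell analytes are drawn as log-normal weights and
#' renormalized per sample so the subsets sum to a sampled total-immune
#' percentage. Progression times are exponential with the group hazard,
#' censored by a per-group coin flip and truncated at the follow-up
#' horizon; overall survival adds an exponential post-progression interval.
#'
#' @param config A [synth_config()].
#' @return An `immune_cohort`; the planted truth (effects, block
#'   correlations, hazards) is attached as attribute `"ground_truth"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sizes <- config$group_sizes[config$group_sizes > 0]
  groups <- rep(names(sizes), sizes)
  n <- length(groups)
  ids <- sprintf("SYN%02d", seq_len(n))

  specs <- config$analytes
  k <- length(specs)
  a_names <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(a_names)) stop("duplicate analyte names in config")
  kinds <- stats::setNames(vapply(specs, `[[`, character(1), "kind"), a_names)

  ## latent correlation matrix: block-diagonal compound symmetry, with the
  ## latent normal rho chosen so the block attains its target Spearman rho
  Sigma <- diag(k)
  blocks <- vapply(specs, function(s) {
    if (is.na(s$corr_block)) NA_character_ else s$corr_block
  }, character(1))
  for (b in unique(stats::na.omit(blocks))) {
    idx <- which(blocks == b)
    if (length(idx) < 2L) next
    rhos <- unique(vapply(specs[idx], `[[`, numeric(1), "block_rho"))
    if (length(rhos) != 1L) stop("inconsistent block_rho within block ", b)
    if (abs(rhos) >= 1) stop("block_rho must satisfy |rho| < 1")
    latent <- 2 * sin(pi * rhos / 6)
    Sigma[idx, idx] <- latent
    diag(Sigma)[idx] <- 1
  }
  Z <- matrix(stats::rnorm(n * k), n, k) %*% chol(Sigma)

  mat <- matrix(NA_real_, n, k, dimnames = list(ids, a_names))
  for (j in seq_len(k)) {
    s <- specs[[j]]
    shift <- s$group_effect[groups]
    mat[, j] <- exp(s$log_mean + shift + s$log_sd * Z[, j])
  }
  ## compositional closure of the cell analytes onto a sampled total
  cell_idx <- which(kinds[a_names] == "cell_percent")
  if (length(cell_idx)) {
    totals <- stats::rnorm(n, config$total_immune_mean, config$total_immune_sd)
    totals <- pmin(pmax(totals, 1), 60)
    w <- mat[, cell_idx, drop = FALSE]
    mat[, cell_idx] <- w / rowSums(w) * totals
  }

  ## tabulated measurement precision: 3 decimals, as a TPM/percent table
  ## would ship (also makes write/read round-trips exact)
  mat <- round(mat, 3)

  ## survival: exponential progression, coin-flip censoring, horizon cutoff
  haz <- config$pfs_hazard[groups]
  pfs_t <- stats::rexp(n, rate = haz)
  pfs_cens <- stats::runif(n) < config$censor_prob[groups]
  over <- pfs_t > config$horizon
  pfs_t[over] <- config$horizon
  pfs_cens <- pfs_cens | over

  os_extra <- stats::rexp(n, rate = config$os_extra_hazard[groups])
  os_t <- ifelse(pfs_cens, pfs_t, pfs_t + os_extra)
  os_cens <- pfs_cens | (os_t > config$horizon)
  os_t <- pmin(os_t, config$horizon)

  records <- data.frame(
    sample_id = ids, group = groups,
    pfs_months = round(pfs_t, 1), pfs_censored = pfs_cens,
    pfs_alt = NA_real_,
    os_months = round(os_t, 1), os_censored = os_cens,
    os_alt = NA_real_,
    maint_bev = FALSE,
    stringsAsFactors = FALSE
  )
  out <- cohort(records, mat, kinds)
  attr(out, "ground_truth") <- list(
    effects = stats::setNames(
      lapply(specs, `[[`, "group_effect"), a_names),
    blocks = stats::setNames(blocks, a_names),
    block_rho = stats::setNames(
      vapply(specs, `[[`, numeric(1), "block_rho"), a_names),
    pfs_hazard = config$pfs_hazard,
    seed = config$seed
  )
  out
}

#' Reference-shaped synthetic fixture
#'
#' A 26-sample synthetic cohort over the bundled 40-analyte panel whose
#' group sizes, group-median locations, gene co-expression block and
#' censoring pattern emulate the profiled ovarian cancer cohort. Intended
#' as a stand-in test fixture; it is synthetic data, not the deposited
#' study data.
#'
#' @param seed Integer seed.
#' @return An `immune_cohort` of 26 samples and 40 analytes.
#' @export
paper_shaped_fixture <- function(seed = 1) {
  generate_cohort(synth_config(seed = seed))
}

#' Write a synthetic cohort and its ground truth to disk
#'
#' Emits the three cohort TSVs ([write_cohort()]) plus a
#' `ground_truth.json` recording the planted effects, block correlations
#' and hazards, for use by test harnesses.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
simulate_cohort_files <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  x <- generate_cohort(config)
  paths <- file.path(outdir, c("analyte_matrix.tsv", "metadata.tsv",
                               "analyte_kinds.tsv"))
  write_cohort(x, paths[1], paths[2], paths[3])
  gt_path <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(attr(x, "ground_truth"), gt_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, gt_path))
}
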