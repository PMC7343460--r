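#' Configuration for the synthetic multi-omics aging cohort
#'
#' Defines the statistical structure the pipeline assumes: subjects with
#' chronological ages drawn uniformly over an age range, a latent biological
#' age (chronological age plus Gaussian deviation), latent phases defined as
#' equal-width bins of biological age, informative gene sets whose mean
#' expression follows per-phase archetype activity profiles, clock CpGs whose
#' M-values drift linearly with biological age, additive per-batch shifts, and
#' inflated residual noise in the last phase on both omics layers.
#'
#' Archetype profiles (per-phase activity, defaults for 4 phases): `primary`
#' peaks in phases 2-3 then drops, `secondary` rises sharply at phase 3,
#' `integrative` rises monotonically and peaks late. For `n_phases != 4` the
#' four-point profiles are linearly interpolated.
#'
#' @param n_subjects cohort size.
#' @param age_range chronological age range in years.
#' @param n_phases number of latent phases (>= 2).
#' @param bio_age_sd SD (years) of the biological-age deviation.
#' @param n_genes,n_cpgs feature counts.
#' @param n_informative_sets,set_size informative gene sets and their size.
#' @param archetypes named list of per-phase activity vectors.
#' @param effect_size multiplier (log2 units) on archetype activity.
#' @param expr_noise_sd,meth_noise_sd residual SDs (log2-TPM / M-value units).
#' @param batch_count,batch_shift_sd number of batches and SD of the per-batch
#'   per-feature additive shift.
#' @param phase4_noise_factor residual-SD multiplier for last-phase subjects
#'   (>= 1), on both omics layers.
#' @param clock_cpg_count CpGs carrying the linear biological-age drift.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 86,
                          age_range = c(21, 76),
                          n_phases = 4,
                          bio_age_sd = 4,
                          n_genes = 2000,
                          n_cpgs = 2000,
                          n_informative_sets = 9,
                          set_size = 20,
                          archetypes = list(
                            primary = c(0.20, 1.00, 0.45, 0.20),
                            secondary = c(0.15, 0.15, 1.00, 0.40),
                            integrative = c(0.10, 0.20, 0.35, 1.00)
                          ),
                          effect_size = 2.5,
                          expr_noise_sd = 0.4,
                          meth_noise_sd = 0.12,
                          batch_count = 2,
                          batch_shift_sd = 0.3,
                          phase4_noise_factor = 2,
                          clock_cpg_count = 150,
                          seed = 1) {
  if (n_phases < 2) abort("`n_phases` must be >= 2.")
  if (phase4_noise_factor < 1) abort("`phase4_noise_factor` must be >= 1.")
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (n_informative_sets * set_size > n_genes) {
    abort("informative sets require more genes than `n_genes` provides.")
  }
  if (clock_cpg_count > n_cpgs) abort("`clock_cpg_count` exceeds `n_cpgs`.")
  structure(
    list(n_subjects = n_subjects, age_range = age_range, n_phases = n_phases,
         bio_age_sd = bio_age_sd, n_genes = n_genes, n_cpgs = n_cpgs,
         n_informative_sets = n_informative_sets, set_size = set_size,
         archetypes = archetypes, effect_size = effect_size,
         expr_noise_sd = expr_noise_sd, meth_noise_sd = meth_noise_sd,
         batch_count = batch_count, batch_shift_sd = batch_shift_sd,
         phase4_noise_factor = phase4_noise_factor,
         clock_cpg_count = clock_cpg_count, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Interpolate a 4-point archetype activity profile to n_phases points.
archetype_profile <- function(activity, n_phases) {
  if (length(activity) == n_phases) return(activity)
  stats::approx(seq(0, 1, length.out = length(activity)), activity,
                xout = seq(0, 1, length.out = n_phases))$y
}

#' Generate a synthetic multi-omics cohort with ground truth
#'
#' Draws a cohort per [cohort_config()]: expression (log2-TPM scale) and
#' methylation (M-value scale) matrices, a subject metadata table, the
#' informative gene-set collection, a linear methylation clock constructed from
#' the generative CpG slopes, and a ground-truth table (biological age, latent
#' phase, batch).
#'
#' The metadata includes a `sun_bathing` binary whose probability increases
#' with biological-age acceleration (bio minus chronological age), giving the
#' age-adjusted logistic association something real to detect.
#'
#' @param config a `cohort_config`.
#' @return A `synthetic_cohort` list: `expr`, `meth` (omics matrices),
#'   `metadata`, `sets`, `clock`, `truth`. `truth` carries the phase
#'   bin breaks and informative-gene map as attributes.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    params <- draw_cohort_params(config)
    subj <- draw_subjects(config)
    out <- realize_cohort(config, params, subj)
  })
  out
}

# Feature-level parameters shared between baseline and follow-up sampling.
draw_cohort_params <- function(config) {
  n_sets <- config$n_informative_sets
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  cpg_ids <- sprintf("cg%06d", seq_len(config$n_cpgs))
  arch_names <- rep(names(config$archetypes),
                    each = ceiling(n_sets / length(config$archetypes)))[seq_len(n_sets)]
  informative <- sample(gene_ids, n_sets * config$set_size)
  set_members <- split(informative, rep(seq_len(n_sets), each = config$set_size))
  set_names <- sprintf("SET_%02d_%s", seq_len(n_sets), toupper(arch_names))
  profiles <- lapply(config$archetypes, archetype_profile, n_phases = config$n_phases)
  clock_cpgs <- sample(cpg_ids, config$clock_cpg_count)
  slopes <- setNames(
    sample(c(-1, 1), config$clock_cpg_count, replace = TRUE) *
      runif(config$clock_cpg_count, 0.03, 0.06),
    clock_cpgs
  )
  batches <- sprintf("batch%d", seq_len(config$batch_count))
  list(
    gene_ids = gene_ids, cpg_ids = cpg_ids,
    gene_mu = setNames(rnorm(config$n_genes, 6, 4), gene_ids),
    cpg_mu = setNames(rnorm(config$n_cpgs, 0, 2), cpg_ids),
    set_members = setNames(set_members, set_names),
    set_archetype = setNames(arch_names, set_names),
    profiles = profiles,
    clock_cpgs = clock_cpgs, slopes = slopes,
    batches = batches,
    batch_shift_expr = lapply(setNames(batches, batches), function(b)
      rnorm(config$n_genes, 0, config$batch_shift_sd)),
    batch_shift_meth = lapply(setNames(batches, batches), function(b)
      rnorm(config$n_cpgs, 0, config$batch_shift_sd))
  )
}

draw_subjects <- function(config) {
  n <- config$n_subjects
  chron <- runif(n, config$age_range[1], config$age_range[2])
  bio <- chron + rnorm(n, 0, config$bio_age_sd)
  # fixed equal-width thresholds over the configured age range; biological
  # ages drifting outside are clamped into the outer bins
  breaks <- seq(config$age_range[1], config$age_range[2],
                length.out = config$n_phases + 1)
  list(
    subject_id = sprintf("S%03d", seq_len(n)),
    chron_age = chron, bio_age = bio, breaks = breaks,
    phase = bin_bio_age(bio, breaks),
    batch = sample(rep_len(sprintf("batch%d", seq_len(config$batch_count)), n))
  )
}

bin_bio_age <- function(bio, breaks) {
  k <- length(breaks) - 1L
  pmin(pmax(findInterval(bio, breaks, rightmost.closed = TRUE), 1L), k)
}

# Sample the omics matrices for a given set of subjects under fixed params.
realize_cohort <- function(config, params, subj) {
  n <- length(subj$subject_id)
  k <- config$n_phases
  noise_mult <- ifelse(subj$phase == k, config$phase4_noise_factor, 1)

  expr <- matrix(rnorm(config$n_genes * n), config$n_genes, n)
  expr <- sweep(expr, 2, config$expr_noise_sd * noise_mult, `*`)
  expr <- expr + params$gene_mu
  rownames(expr) <- params$gene_ids
  for (s in names(params$set_members)) {
    prof <- params$profiles[[params$set_archetype[[s]]]]
    shift <- config$effect_size * prof[subj$phase]
    expr[params$set_members[[s]], ] <-
      expr[params$set_members[[s]], , drop = FALSE] +
      matrix(shift, config$set_size, n, byrow = TRUE)
  }
  meth <- matrix(rnorm(config$n_cpgs * n), config$n_cpgs, n)
  meth <- sweep(meth, 2, config$meth_noise_sd * noise_mult, `*`)
  meth <- meth + params$cpg_mu
  rownames(meth) <- params$cpg_ids
  age_centered <- subj$bio_age - mean(config$age_range)
  meth[params$clock_cpgs, ] <- meth[params$clock_cpgs, , drop = FALSE] +
    outer(params$slopes, age_centered)
  for (b in params$batches) {
    in_b <- subj$batch == b
    expr[, in_b] <- expr[, in_b, drop = FALSE] + params$batch_shift_expr[[b]]
    meth[, in_b] <- meth[, in_b, drop = FALSE] + params$batch_shift_meth[[b]]
  }
  colnames(expr) <- colnames(meth) <- subj$subject_id

  m <- config$clock_cpg_count
  coefs <- 1 / (m * params$slopes)
  clock <- clock_model(
    coefs,
    intercept = mean(config$age_range) - sum(params$cpg_mu[params$clock_cpgs] * coefs),
    input_scale = "m_value"
  )

  truth <- tibble::tibble(
    subject_id = subj$subject_id, chron_age = subj$chron_age,
    bio_age = subj$bio_age, phase = subj$phase, batch = subj$batch
  )
  attr(truth, "breaks") <- subj$breaks
  attr(truth, "informative_genes") <- unlist(params$set_members, use.names = FALSE)
  attr(truth, "set_archetype") <- params$set_archetype

  sun_prob <- plogis(-1 + 0.15 * (subj$bio_age - subj$chron_age))
  metadata <- tibble::tibble(
    subject_id = subj$subject_id,
    chron_age = subj$chron_age,
    batch = subj$batch,
    timepoint = 1L,
    bmi = rnorm(n, 24, 3),
    sun_bathing = stats::rbinom(n, 1, sun_prob)
  )

  structure(
    list(
      expr = omics_matrix(expr, "expression", "log2_tpm", batch = subj$batch),
      meth = omics_matrix(meth, "methylation", "m_value", batch = subj$batch),
      metadata = metadata,
      sets = gene_sets(params$set_members,
                       descriptions = paste0("archetype:", params$set_archetype)),
      clock = clock,
      truth = truth,
      config = config, params = params, subjects = subj
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d genes, %d CpGs, %d phases, %d informative sets\n",
    nrow(x$truth), x$config$n_genes, x$config$n_cpgs, x$config$n_phases,
    nrow(x$sets)
  ))
  invisible(x)
}

#' Simulate a longitudinal follow-up measurement
#'
#' Re-measures a subset of the cohort `years` later: chronological and
#' biological ages advance by `years`, feature-level generative parameters
#' (baselines, archetype shifts, clock slopes, batch shifts) are reused, and
#' residual noise is redrawn. True phases at follow-up are assigned with the
#' baseline cohort's bin breaks, so slow drift moves subjects forward along
#' the phase axis, never backward.
#'
#' @param cohort a `synthetic_cohort`.
#' @param years elapsed time in years.
#' @param n_subjects how many subjects to re-invite (sampled without
#'   replacement; default 31).
#' @param seed seed for subject sampling and new measurement noise.
#' @return A `synthetic_cohort` restricted to the re-invited subjects at the
#'   second timepoint (metadata `timepoint = 2`).
#' @export
generate_followup <- function(cohort, years = 3, n_subjects = 31, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  config <- cohort$config
  with_local_seed(seed, {
    keep <- sort(sample.int(length(cohort$subjects$subject_id),
                            min(n_subjects, length(cohort$subjects$subject_id))))
    subj <- cohort$subjects
    subj2 <- list(
      subject_id = subj$subject_id[keep],
      chron_age = subj$chron_age[keep] + years,
      bio_age = subj$bio_age[keep] + years,
      breaks = subj$breaks,
      batch = subj$batch[keep]
    )
    subj2$phase <- bin_bio_age(subj2$bio_age, subj$breaks)
    out <- realize_cohort(config, cohort$params, subj2)
  })
  out$metadata$timepoint <- 2L
  out
}

#' Draw negative-control gene sets from uninformative genes
#'
#' Samples gene sets uniformly from the genes that carry no phase signal in a
#' synthetic cohort, for use as chance-level baselines in predictivity
#' analyses.
#'
#' @param cohort a `synthetic_cohort`.
#' @param n number of null sets.
#' @param size genes per set.
#' @param seed sampling seed.
#' @return A `gene_sets` collection of `n` sets named `NULL_01`, ...
#' @export
generate_null_sets <- function(cohort, n, size, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  pool <- setdiff(feature_ids(cohort$expr),
                  attr(cohort$truth, "informative_genes"))
  if (n == 0) return(gene_sets(list()))
  if (size > length(pool)) {
    abort(sprintf("requested null-set size %d exceeds the %d uninformative genes.",
                  size, length(pool)))
  }
  with_local_seed(seed, {
    sets <- lapply(seq_len(n), function(i) sample(pool, size))
  })
  gene_sets(setNames(sets, sprintf("NULL_%02d", seq_len(n))))
}
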