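#' Configuration for a simulated co-culture mimic screen
#'
#' Describes the layout and planted effects of an arrayed miRNA-mimic
#' co-culture screen: a library of unique mature miRNA sequences (some
#' represented by more than one library entry) spread over 96-well plates,
#' run in replicate screens, with two imaging channels per well (unlabelled
#' fibroblasts and GFP-labelled cancer cells). Defaults mirror a genome-scale
#' screen: 875 unique sequences in 988 library entries, duplicate screens,
#' 8000 fibroblasts and 3500 cancer cells seeded per well.
#'
#' @param n_mirnas Number of unique mature miRNA sequences.
#' @param n_duplicate_entries Library entries mapping to sequences already in
#'   the library (total entries per screen = `n_mirnas + n_duplicate_entries`).
#' @param plate_capacity Sample wells per plate; together with
#'   `controls_per_plate` it must fit a 96-well plate.
#' @param n_screens Number of replicate screens.
#' @param baseline_fib,baseline_cancer Expected per-well nuclei counts
#'   (summed over imaging fields) for each channel under a null mimic.
#' @param frac_inhibitory,frac_stimulatory Fractions of miRNAs with planted
#'   growth effects; the remainder are null (effect 1).
#' @param effect_low Length-2 bounds of the multiplicative inhibitory effect.
#' @param effect_high Length-2 bounds of the stimulatory effect.
#' @param cross_effect_corr Copula correlation between a miRNA's fibroblast
#'   and cancer-channel effect magnitudes.
#' @param noise_cv Coefficient of variation of multiplicative well noise.
#' @param controls_per_plate Control wells added to each plate.
#' @param control_id Entity label used for control wells.
#' @param seed Default RNG seed used by [sim_screen()].
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_mirnas = 875, n_duplicate_entries = 113,
                              plate_capacity = 80, n_screens = 2,
                              baseline_fib = 8000, baseline_cancer = 3500,
                              frac_inhibitory = 0.1, frac_stimulatory = 0.1,
                              effect_low = c(0.6, 0.9),
                              effect_high = c(1.1, 1.4),
                              cross_effect_corr = 0.35, noise_cv = 0.1,
                              controls_per_plate = 4, control_id = "miR-C",
                              seed = NULL) {
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  n_duplicate_entries <- check_count(n_duplicate_entries,
                                     "n_duplicate_entries", positive = FALSE)
  plate_capacity <- check_count(plate_capacity, "plate_capacity")
  n_screens <- check_count(n_screens, "n_screens")
  controls_per_plate <- check_count(controls_per_plate, "controls_per_plate",
                                    positive = FALSE)
  if (baseline_fib <= 0 || baseline_cancer <= 0) {
    abort("Baseline well counts must be positive.")
  }
  check_fraction(frac_inhibitory, "frac_inhibitory")
  check_fraction(frac_stimulatory, "frac_stimulatory")
  if (frac_inhibitory + frac_stimulatory > 1) {
    abort("`frac_inhibitory` + `frac_stimulatory` must not exceed 1.")
  }
  if (length(effect_low) != 2 || any(effect_low <= 0) || diff(effect_low) < 0 ||
      length(effect_high) != 2 || any(effect_high <= 0) || diff(effect_high) < 0) {
    abort("Effect bounds must be positive, non-decreasing length-2 vectors.")
  }
  if (abs(cross_effect_corr) > 1) abort("`cross_effect_corr` must lie in [-1, 1].")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  if (plate_capacity + controls_per_plate > 96) {
    abort("`plate_capacity` + `controls_per_plate` exceeds a 96-well plate.")
  }
  structure(
    list(n_mirnas = n_mirnas, n_duplicate_entries = n_duplicate_entries,
         plate_capacity = plate_capacity, n_screens = n_screens,
         baseline_fib = baseline_fib, baseline_cancer = baseline_cancer,
         frac_inhibitory = frac_inhibitory, frac_stimulatory = frac_stimulatory,
         effect_low = effect_low, effect_high = effect_high,
         cross_effect_corr = cross_effect_corr, noise_cv = noise_cv,
         controls_per_plate = controls_per_plate, control_id = control_id,
         seed = seed),
    class = "screen_sim_config")
}

well_labels <- function(n) {
  # row-major labels on a 96-well grid: A01, A02, ..., H12
  rows <- rep(LETTERS[1:8], each = 12)
  cols <- rep(1:12, times = 8)
  sprintf("%s%02d", rows[seq_len(n)], cols[seq_len(n)])
}

#' Simulate an arrayed miRNA-mimic co-culture screen
#'
#' Generates per-well two-channel nuclei counts with planted per-miRNA growth
#' effects. Each unique sequence receives a multiplicative effect per channel
#' (inhibitory, stimulatory, or null); duplicate library entries share the
#' effect of their parent sequence. Within each screen replicate, entries are
#' laid out in random order across plates, each plate carrying additional
#' control wells with effect 1. Counts are drawn as
#' `round(baseline x effect x lognormal noise)` with the configured CV, so a
#' noise-free run returns exact baselines under null effects.
#'
#' @param config A [screen_sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A list of class `screen_sim` with elements `wells` (one row per
#'   plate/well/replicate), `sequence_map` (`entity_id` -> `mirna_id`), and
#'   `truth` (per-miRNA planted class and channel effects).
#' @examples
#' sim <- sim_screen(screen_sim_config(n_mirnas = 20, n_duplicate_entries = 4,
#'                                     plate_capacity = 24, seed = 1))
#' head(sim$wells)
#' @export
sim_screen <- function(config = screen_sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(seed, {
    n <- config$n_mirnas
    mirna_id <- sprintf("mir-%04d", seq_len(n))

    n_inh <- round(config$frac_inhibitory * n)
    n_stim <- round(config$frac_stimulatory * n)
    class <- rep("null", n)
    idx <- sample.int(n, n_inh + n_stim)
    class[idx[seq_len(n_inh)]] <- "inhibitory"
    class[idx[seq_len(n_stim) + n_inh]] <- "stimulatory"

    # Gaussian copula couples the two channels' effect magnitudes.
    r <- config$cross_effect_corr
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    u <- cbind(pnorm(z1), pnorm(z2))
    effect_for <- function(u) {
      e <- rep(1, n)
      e[class == "inhibitory"] <- config$effect_low[1] +
        u[class == "inhibitory"] * diff(config$effect_low)
      e[class == "stimulatory"] <- config$effect_high[1] +
        u[class == "stimulatory"] * diff(config$effect_high)
      e
    }
    effect_fib <- effect_for(u[, 1])
    effect_cancer <- effect_for(u[, 2])

    truth <- tibble::tibble(mirna_id = mirna_id, class = class,
                            effect_fib = effect_fib,
                            effect_cancer = effect_cancer)

    n_entries <- n + config$n_duplicate_entries
    parent <- c(seq_len(n),
                sample.int(n, config$n_duplicate_entries,
                           replace = config$n_duplicate_entries > n))
    sequence_map <- tibble::tibble(
      entity_id = sprintf("ent-%04d", seq_len(n_entries)),
      mirna_id = mirna_id[parent])

    n_plates <- ceiling(n_entries / config$plate_capacity)
    screens <- lapply(seq_len(config$n_screens), function(s) {
      ord <- sample.int(n_entries)
      plate_of <- rep(seq_len(n_plates),
                      each = config$plate_capacity)[seq_len(n_entries)]
      sample_wells <- tibble::tibble(
        plate_id = sprintf("S%d-P%02d", s, plate_of),
        entity_id = sequence_map$entity_id[ord],
        effect_fib = effect_fib[parent[ord]],
        effect_cancer = effect_cancer[parent[ord]])
      sample_wells <- sample_wells |>
        dplyr::group_by(.data$plate_id) |>
        dplyr::mutate(well = well_labels(96)[seq_len(dplyr::n())]) |>
        dplyr::ungroup()
      ctrl <- tibble::tibble(
        plate_id = rep(sprintf("S%d-P%02d", s, seq_len(n_plates)),
                       each = config$controls_per_plate),
        entity_id = config$control_id,
        effect_fib = 1, effect_cancer = 1) |>
        dplyr::group_by(.data$plate_id) |>
        dplyr::mutate(well = well_labels(96)[config$plate_capacity +
                                               seq_len(dplyr::n())]) |>
        dplyr::ungroup()
      dplyr::bind_rows(sample_wells, ctrl) |>
        dplyr::mutate(screen_replicate = s)
    })
    wells <- dplyr::bind_rows(screens)
    nw <- nrow(wells)
    wells <- wells |>
      dplyr::mutate(
        fib_count = as.integer(round(config$baseline_fib * .data$effect_fib *
                                       ln_noise(nw, config$noise_cv))),
        cancer_count = as.integer(round(config$baseline_cancer *
                                          .data$effect_cancer *
                                          ln_noise(nw, config$noise_cv))),
        n_fields = 4L) |>
      dplyr::select("plate_id", "well", "entity_id", "screen_replicate",
                    "fib_count", "cancer_count", "n_fields")

    structure(list(wells = wells, sequence_map = sequence_map, truth = truth,
                   config = config),
              class = "screen_sim")
  })
}

#' Simulate per-algorithm miRNA-target prediction tables
#'
#' Plants a seed-family structure: miRNAs are partitioned into families, each
#' family shares a core target-gene set (disjoint across families), and each
#' miRNA adds private targets. Each of `n_algorithms` prediction algorithms
#' reports each true target independently with probability `1 - per_algo_dropout`
#' and each non-target with probability `per_algo_fp`.
#'
#' @param n_mirnas,n_genes,n_families Universe sizes; families partition the
#'   miRNAs as evenly as possible.
#' @param core_targets_per_family,private_targets_per_mirna Planted set sizes.
#' @param per_algo_dropout,per_algo_fp Per-algorithm miss and false-positive
#'   rates, both in \[0, 1\].
#' @param n_algorithms Number of algorithms (default 6).
#' @param algorithms Optional algorithm names (defaults to six standard
#'   prediction tools).
#' @param seed RNG seed.
#' @return A list of class `prediction_sim` with `predictions` (long tibble
#'   `algorithm_id, mirna_id, gene_id`), `truth$families`, and
#'   `truth$target_sets` (named list of true target sets).
#' @export
sim_predictions <- function(n_mirnas = 120, n_genes = 500, n_families = 11,
                            core_targets_per_family = 30,
                            private_targets_per_mirna = 10,
                            per_algo_dropout = 0.1, per_algo_fp = 0.01,
                            n_algorithms = 6, algorithms = NULL, seed = NULL) {
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  n_genes <- check_count(n_genes, "n_genes")
  n_families <- check_count(n_families, "n_families")
  check_fraction(per_algo_dropout, "per_algo_dropout")
  check_fraction(per_algo_fp, "per_algo_fp")
  if (n_families > n_mirnas) abort("`n_families` must not exceed `n_mirnas`.")
  if (n_families * core_targets_per_family > n_genes) {
    abort("Family core target sets exceed the gene universe.")
  }
  if (is.null(algorithms)) {
    default <- c("DIANA-microT-CDS", "microrna.org", "miRDB", "PITA", "RNA22",
                 "TargetScan")
    algorithms <- if (n_algorithms <= length(default)) {
      default[seq_len(n_algorithms)]
    } else {
      sprintf("algo-%02d", seq_len(n_algorithms))
    }
  }
  stopifnot(length(algorithms) == n_algorithms)

  with_seed(seed, {
    mirna_id <- sprintf("mir-%03d", seq_len(n_mirnas))
    gene_id <- sprintf("gene-%04d", seq_len(n_genes))
    family <- sort(rep_len(seq_len(n_families), n_mirnas))

    core_pool <- sample.int(n_genes, n_families * core_targets_per_family)
    cores <- split(core_pool, rep(seq_len(n_families),
                                  each = core_targets_per_family))

    truth_mat <- matrix(FALSE, n_mirnas, n_genes,
                        dimnames = list(mirna_id, gene_id))
    for (i in seq_len(n_mirnas)) {
      core <- cores[[family[i]]]
      pool <- setdiff(seq_len(n_genes), core)
      priv <- sample(pool, min(private_targets_per_mirna, length(pool)))
      truth_mat[i, c(core, priv)] <- TRUE
    }

    preds <- lapply(seq_len(n_algorithms), function(a) {
      keep <- truth_mat & (runif(length(truth_mat)) < 1 - per_algo_dropout)
      fp <- (!truth_mat) & (runif(length(truth_mat)) < per_algo_fp)
      hit <- which(keep | fp, arr.ind = TRUE)
      tibble::tibble(algorithm_id = algorithms[a],
                     mirna_id = mirna_id[hit[, 1]],
                     gene_id = gene_id[hit[, 2]])
    })
    predictions <- dplyr::bind_rows(preds) |>
      dplyr::arrange(.data$algorithm_id, .data$mirna_id, .data$gene_id)

    target_sets <- lapply(seq_len(n_mirnas),
                          function(i) gene_id[truth_mat[i, ]])
    names(target_sets) <- mirna_id

    structure(
      list(predictions = predictions,
           truth = list(
             families = tibble::tibble(
               mirna_id = mirna_id,
               family = sprintf("family-%02d", family)),
             target_sets = target_sets),
           algorithms = algorithms),
      class = "prediction_sim")
  })
}

#' Simulate a multiplex secretome panel pair
#'
#' Generates control and treated replicate concentrations for a panel of
#' secreted factors (91 by default, matching a combined cytokine/angiogenesis/
#' MMP multiplex design). A planted subset is perturbed by a multiplicative
#' effect drawn outside the unchanged band (below 0.75 or above 1.25, within
#' `effect_range`); the first perturbed factor is an HGF-like near-depletion
#' fixed at `effect_range[1]`. Unperturbed factors have effect exactly 1.
#'
#' @param n_factors Panel size.
#' @param n_perturbed Number of perturbed factors.
#' @param effect_range Envelope of perturbation effects; must extend below
#'   0.75 and (when more than one perturbation is requested) above 1.25.
#' @param n_replicates Replicates per condition (default biological
#'   triplicates).
#' @param cv Coefficient of variation of multiplicative measurement noise.
#' @param baseline_range Range (pg/ml) of log-uniform factor baselines.
#' @param seed RNG seed.
#' @return A list of class `secretome_sim` with `panel` (long tibble
#'   `factor_id, condition, replicate, concentration`) and `truth`
#'   (per-factor true effect and percent of control).
#' @export
sim_secretome <- function(n_factors = 91, n_perturbed = 26,
                          effect_range = c(0.02, 2), n_replicates = 3,
                          cv = 0.1, baseline_range = c(10, 5000),
                          seed = NULL) {
  n_factors <- check_count(n_factors, "n_factors")
  n_perturbed <- check_count(n_perturbed, "n_perturbed", positive = FALSE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (n_perturbed > n_factors) abort("`n_perturbed` must not exceed `n_factors`.")
  if (cv < 0) abort("`cv` must be non-negative.")
  if (n_perturbed > 0 && effect_range[1] >= 0.75) {
    abort("`effect_range` must extend below 0.75 to plant down-perturbations.")
  }

  with_seed(seed, {
    factor_id <- c("HGF", sprintf("factor-%02d", seq_len(n_factors))[-1])
    effect <- rep(1, n_factors)
    if (n_perturbed > 0) {
      perturbed <- c(1L, sample(2:n_factors, n_perturbed - 1L))
      # HGF-like near-depletion; remaining perturbations split between the
      # down-range [min, 0.75) and (when available) the up-range (1.25, max].
      effect[1] <- effect_range[1]
      rest <- perturbed[-1]
      if (length(rest) > 0) {
        up_ok <- effect_range[2] > 1.25
        n_up <- if (up_ok) floor(length(rest) / 2) else 0L
        up <- if (n_up > 0) sample(rest, n_up) else integer(0)
        down <- setdiff(rest, up)
        effect[down] <- runif(length(down), effect_range[1], 0.75)
        effect[up] <- runif(length(up), 1.25, effect_range[2])
      }
    } else {
      perturbed <- integer(0)
    }
    baseline <- exp(runif(n_factors, log(baseline_range[1]),
                          log(baseline_range[2])))
    grid <- tidyr::expand_grid(
      factor_id = factor_id,
      condition = c("control", "treated"),
      replicate = seq_len(n_replicates))
    idx <- match(grid$factor_id, factor_id)
    eff_row <- ifelse(grid$condition == "treated", effect[idx], 1)
    grid$concentration <- baseline[idx] * eff_row *
      ln_noise(nrow(grid), cv)

    truth <- tibble::tibble(factor_id = factor_id,
                            baseline = baseline,
                            true_effect = effect,
                            true_percent = 100 * effect,
                            perturbed = seq_len(n_factors) %in% perturbed)
    structure(list(panel = grid, truth = truth), class = "secretome_sim")
  })
}

#' Simulate a wound-closure (gap area) time course
#'
#' Produces a monotone-in-expectation decreasing gap-area series whose
#' noise-free area reaches half the initial area exactly at `true_thalf`.
#' Two shapes are available: `"linear"` (constant closure rate, reaching zero
#' at `2 * true_thalf`) and `"logistic"` (sigmoidal closure with scale
#' `true_thalf / 4`, anchored so the half-area crossing is exact).
#' If `horizon < true_thalf` the series cannot reach half closure and is
#' flagged censored in the truth table.
#'
#' @param true_thalf True half-closure time, hours.
#' @param model `"linear"` or `"logistic"`.
#' @param dt Sampling interval, hours.
#' @param horizon Last observation time, hours.
#' @param noise_cv CV of multiplicative area measurement noise.
#' @param initial_area Gap area at time zero (arbitrary units).
#' @param condition Condition label carried into the series.
#' @param seed RNG seed.
#' @return A list of class `wound_sim` with `series` (tibble
#'   `condition, time_h, gap_area`) and `truth`.
#' @export
sim_wound <- function(true_thalf = 12, model = c("logistic", "linear"),
                      dt = 1, horizon = 24, noise_cv = 0,
                      initial_area = 100, condition = "sim", seed = NULL) {
  model <- match.arg(model)
  if (dt <= 0) abort("`dt` must be positive.")
  if (true_thalf <= 0) abort("`true_thalf` must be positive.")
  if (horizon < dt) abort("`horizon` must cover at least one interval.")

  with_seed(seed, {
    times <- seq(0, horizon, by = dt)
    area <- switch(model,
      linear = initial_area * pmax(0, 1 - times / (2 * true_thalf)),
      logistic = {
        s <- true_thalf / 4
        b <- exp(true_thalf / s)       # > 2, so the anchor below exists
        t0 <- s * log(b - 2)
        f <- 1 / (1 + exp((times - t0) / s))
        initial_area * f / f[1]
      })
    area <- area * ln_noise(length(area), noise_cv)
    structure(
      list(series = tibble::tibble(condition = condition, time_h = times,
                                   gap_area = area),
           truth = tibble::tibble(condition = condition,
                                  true_thalf = true_thalf, model = model,
                                  censored = horizon < true_thalf)),
      class = "wound_sim")
  })
}

#' Simulate a two-arm cohort with a smoking-like continuous exposure
#'
#' Subject analyte levels (e.g. plasma HGF or fibroblast miR-16 intensity)
#' are lognormal with the specified per-arm medians and common log-scale sd.
#' A continuous exposure (pack-years-like) is coupled to the analyte through
#' a Gaussian copula calibrated so the population Spearman correlation equals
#' `exposure_rho` (Pearson latent correlation `2 sin(pi rho / 6)`).
#'
#' @param n_per_group Arm sizes (length-2 or recycled to the number of
#'   medians).
#' @param group_medians Named or unnamed per-arm analyte medians (> 0).
#' @param lognormal_sigma Log-scale standard deviation of the analyte.
#' @param exposure_rho Target Spearman correlation between exposure and
#'   analyte, in \[-1, 1\].
#' @param exposure_meanlog,exposure_sdlog Lognormal parameters of the
#'   exposure's marginal distribution.
#' @param seed RNG seed.
#' @return A list of class `cohort_sim` with `records` (tibble
#'   `subject_id, group, analyte, pack_years`) and `truth`.
#' @export
sim_cohort <- function(n_per_group = c(45, 45), group_medians = c(1, 1),
                       lognormal_sigma = 0.5, exposure_rho = 0,
                       exposure_meanlog = log(30), exposure_sdlog = 0.5,
                       seed = NULL) {
  if (any(group_medians <= 0)) abort("`group_medians` must be positive.")
  if (abs(exposure_rho) > 1) abort("`exposure_rho` must lie in [-1, 1].")
  if (lognormal_sigma < 0) abort("`lognormal_sigma` must be non-negative.")
  k <- length(group_medians)
  n_per_group <- rep_len(n_per_group, k)
  labels <- names(group_medians) %||% sprintf("group%d", seq_len(k))

  with_seed(seed, {
    n <- sum(n_per_group)
    group <- rep(labels, times = n_per_group)
    med <- rep(group_medians, times = n_per_group)
    z1 <- rnorm(n)
    rp <- 2 * sin(pi * exposure_rho / 6)
    z2 <- rp * z1 + sqrt(1 - rp^2) * rnorm(n)
    records <- tibble::tibble(
      subject_id = sprintf("subj-%03d", seq_len(n)),
      group = group,
      analyte = med * exp(lognormal_sigma * z1),
      pack_years = qlnorm(pnorm(z2), exposure_meanlog, exposure_sdlog))
    structure(
      list(records = records,
           truth = list(group_medians = setNames(group_medians, labels),
                        exposure_rho = exposure_rho,
                        latent_pearson = rp)),
      class = "cohort_sim")
  })
}
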