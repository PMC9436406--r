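#' Default treatment conditions for a simulated slice-culture experiment
#'
#' Untreated 72 h control, three sodium selenite doses (5, 15, 30 uM) and
#' gemcitabine at 1 uM. The `selenite` flag marks which conditions follow the
#' selenite dose-response model; gemcitabine acts only in responder patients.
#'
#' @return A data.frame with columns `condition`, `dose_um`, `selenite`.
#' @export
default_conditions <- function() {
  data.frame(
    condition = c("control_72h", "se5", "se15", "se30", "gem1"),
    dose_um   = c(0, 5, 15, 30, 1),
    selenite  = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic slice-culture cohort generator
#'
#' Bundles every tunable parameter of [generate_cohort()] and validates it.
#' Defaults emulate an 8-patient pancreatic cancer cohort treated in duplicate
#' slices under five conditions, with a steep selenite dose-response
#' (minimal effect at 5 uM, >90% tumor damage at 15-30 uM) and a largely
#' ineffective gemcitabine arm.
#'
#' @param n_patients number of tumor cultures (patients).
#' @param conditions data.frame as returned by [default_conditions()]:
#'   columns `condition` (label), `dose_um` (dose in uM) and `selenite`
#'   (logical; non-selenite treated conditions use the responder model).
#' @param duplicates_per_condition slices cultured per patient x condition.
#' @param slices_per_tumor_mean,slices_per_tumor_range mean and range of the
#'   number of slices a vibratome run yields per tumor (metadata only; the
#'   number of slices actually cultured is set by `conditions` and
#'   `duplicates_per_condition`).
#' @param perimeter_mean_um mean annotated slice perimeter, micrometres.
#' @param v0_alpha,v0_beta Beta shape parameters for the baseline (untreated)
#'   viable fraction of the cancer cell outgrowth.
#' @param emax maximal fractional reduction of the viable fraction, in [0,1].
#' @param ec50_um dose (uM) of half-maximal effect; must be > 0.
#' @param hill Hill exponent (> 0) controlling dose-response steepness.
#' @param outgrowth0 baseline outgrowth length as a fraction of the slice
#'   perimeter, in [0,1].
#' @param outgrowth_decline maximal fractional reduction of the outgrowth
#'   fraction at saturating dose, in [0,1].
#' @param noise_sd standard deviation of slice-level noise on the logit scale
#'   (applied to both the viable fraction and the outgrowth fraction).
#' @param area_mode_patients number of patients quantified by viable/damaged
#'   tumor area within the slice instead of surface outgrowth (the first
#'   `area_mode_patients` cultures of the cohort).
#' @param gem_responder_prob per-patient probability of responding to the
#'   non-selenite (gemcitabine) arm.
#' @param seed master integer seed; per-patient substreams are derived from
#'   it by fixed offsets, so enlarging the cohort never reshuffles earlier
#'   patients.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_patients = 8,
                             conditions = default_conditions(),
                             duplicates_per_condition = 2,
                             slices_per_tumor_mean = 14,
                             slices_per_tumor_range = c(9, 18),
                             perimeter_mean_um = 20000,
                             v0_alpha = 8,
                             v0_beta = 2,
                             emax = 0.99,
                             ec50_um = 7,
                             hill = 4,
                             outgrowth0 = 0.55,
                             outgrowth_decline = 0.75,
                             noise_sd = 0.3,
                             area_mode_patients = 2,
                             gem_responder_prob = 1 / 8,
                             seed = 1L) {
  stopifnot(
    is.data.frame(conditions),
    all(c("condition", "dose_um", "selenite") %in% names(conditions)),
    !anyDuplicated(conditions$condition),
    all(conditions$dose_um >= 0)
  )
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (duplicates_per_condition < 1) stop("duplicates_per_condition must be >= 1")
  for (f in c("emax", "outgrowth0", "outgrowth_decline", "gem_responder_prob")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(sprintf("%s must be a fraction in [0, 1]", f))
  }
  if (ec50_um <= 0) stop("ec50_um must be > 0")
  if (hill <= 0) stop("hill must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (v0_alpha <= 0 || v0_beta <= 0) stop("Beta shape parameters must be > 0")
  if (area_mode_patients < 0 || area_mode_patients > n_patients)
    stop("area_mode_patients must be between 0 and n_patients")
  if (perimeter_mean_um <= 0) stop("perimeter_mean_um must be > 0")

  cfg <- list(
    n_patients = as.integer(n_patients),
    conditions = conditions,
    duplicates_per_condition = as.integer(duplicates_per_condition),
    slices_per_tumor_mean = slices_per_tumor_mean,
    slices_per_tumor_range = slices_per_tumor_range,
    perimeter_mean_um = perimeter_mean_um,
    v0_alpha = v0_alpha, v0_beta = v0_beta,
    emax = emax, ec50_um = ec50_um, hill = hill,
    outgrowth0 = outgrowth0, outgrowth_decline = outgrowth_decline,
    noise_sd = noise_sd,
    area_mode_patients = as.integer(area_mode_patients),
    gem_responder_prob = gem_responder_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic slice-culture cohort configuration\n")
  cat(sprintf("  %d patients (%d area-mode), %d duplicate slice(s) per condition\n",
              x$n_patients, x$area_mode_patients, x$duplicates_per_condition))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s (%g uM)", x$conditions$condition, x$conditions$dose_um),
                    collapse = ", ")))
  cat(sprintf("  dose-response: emax = %g, ec50 = %g uM, hill = %g\n",
              x$emax, x$ec50_um, x$hill))
  cat(sprintf("  baseline viable fraction ~ Beta(%g, %g); outgrowth0 = %g\n",
              x$v0_alpha, x$v0_beta, x$outgrowth0))
  cat(sprintf("  logit noise sd = %g; seed = %d\n", x$noise_sd, x$seed))
  invisible(x)
}

#' Emax/Hill dose-response for the viable fraction
#'
#' Expected viable fraction of the cancer cell outgrowth after treatment at
#' `dose`, given a baseline viable fraction `v0`:
#' `v0 * (1 - emax * dose^hill / (dose^hill + ec50^hill))`.
#' Monotone non-increasing in dose.
#'
#' @param v0 baseline viable fraction in [0, 1] (vectorised).
#' @param dose dose in uM, >= 0 (vectorised).
#' @param emax maximal fractional effect in [0, 1].
#' @param ec50 dose of half-maximal effect, > 0 uM.
#' @param hill Hill exponent, > 0.
#' @return Expected viable fraction, same length as `v0`/`dose`.
#' @examples
#' dose_response_viable_fraction(0.8, 0, emax = 1, ec50 = 7, hill = 4)   # 0.8
#' dose_response_viable_fraction(0.8, 7, emax = 1, ec50 = 7, hill = 4)   # 0.4
#' @export
dose_response_viable_fraction <- function(v0, dose, emax, ec50, hill) {
  if (any(v0 < 0 | v0 > 1)) stop("v0 must be in [0, 1]")
  if (any(emax < 0 | emax > 1)) stop("emax must be in [0, 1]")
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(ec50 <= 0)) stop("ec50 must be > 0")
  if (any(hill <= 0)) stop("hill must be > 0")
  dh <- dose^hill
  v0 * (1 - emax * dh / (dh + ec50^hill))
}

# Run code under a derived seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-patient substream seed (kept below 2^31).
patient_seed <- function(master, patient_index) {
  as.integer((as.numeric(master) + 7919 * patient_index) %% .Machine$integer.max)
}

# Logit-normal perturbation of a fraction; exact pass-through when sd == 0 so
# noise-free cohorts recover ground truth bit-for-bit.
perturb_fraction <- function(p, sd) {
  if (sd == 0) return(p)
  p_clamped <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  stats::plogis(stats::qlogis(p_clamped) + stats::rnorm(length(p), 0, sd))
}

viable_class_names  <- c("flat", "cubic", "cylindrical", "clear")
damaged_class_names <- c("swollen", "necro_apoptotic")

# Symmetric (flat Dirichlet) random composition over k parts.
random_composition <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

#' Generate a synthetic annotation-measurement cohort
#'
#' Simulates the annotation tables a whole-slide measurement export would
#' produce for a slice-culture drug test: for outgrowth-mode patients, one
#' perimeter-length record per slice plus per-morphology outgrowth-length
#' records (viable length split across flat/cubic/cylindrical/clear, damaged
#' length across swollen/necro_apoptotic); for area-mode patients, viable and
#' damaged tumor-area records. Duplicate slices share the patient x condition
#' expectation and differ by logit-normal noise. The generator also returns
#' the ground truth so parameter-recovery can be tested.
#'
#' @param config a [synthetic_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{annotations}{data.frame with columns `culture_id`, `slice_id`,
#'       `replicate`, `condition`, `dose_um`, `annotation_class`,
#'       `measure_kind`, `value`, `unit`.}
#'     \item{truth}{data.frame with one row per patient x condition:
#'       `culture_id`, `condition`, `mode`, `v0`, `viable_frac`,
#'       `outgrowth_frac`, `gem_responder`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cond <- config$conditions
  patients <- lapply(seq_len(config$n_patients), function(p) {
    local_seed(patient_seed(config$seed, p), generate_patient(config, p))
  })
  list(
    annotations = do.call(rbind, lapply(patients, `[[`, "annotations")),
    truth       = do.call(rbind, lapply(patients, `[[`, "truth")),
    config      = config
  )
}

# One patient's slices under every condition; called inside the patient's
# RNG substream so draw order is fixed regardless of cohort size.
generate_patient <- function(config, p) {
  cond <- config$conditions
  culture <- sprintf("DT%d", p)
  mode <- if (p <= config$area_mode_patients) "area" else "outgrowth"

  v0 <- stats::rbeta(1, config$v0_alpha, config$v0_beta)
  gem_responder <- stats::runif(1) < config$gem_responder_prob

  frac_effect <- function(dose) {
    dh <- dose^config$hill
    dh / (dh + config$ec50_um^config$hill)
  }
  expected <- lapply(seq_len(nrow(cond)), function(i) {
    if (cond$selenite[i] || cond$dose_um[i] == 0) {
      vf <- dose_response_viable_fraction(v0, cond$dose_um[i], config$emax,
                                          config$ec50_um, config$hill)
      of <- config$outgrowth0 * (1 - config$outgrowth_decline * frac_effect(cond$dose_um[i]))
    } else if (gem_responder) {
      vf <- v0 * (1 - config$emax)
      of <- config$outgrowth0 * (1 - config$outgrowth_decline)
    } else {
      vf <- v0
      of <- config$outgrowth0
    }
    c(viable_frac = vf, outgrowth_frac = of)
  })
  expected <- do.call(rbind, expected)

  truth <- data.frame(
    culture_id = culture,
    condition = cond$condition,
    mode = mode,
    v0 = v0,
    viable_frac = expected[, "viable_frac"],
    outgrowth_frac = expected[, "outgrowth_frac"],
    gem_responder = gem_responder,
    stringsAsFactors = FALSE
  )

  rows <- list()
  for (i in seq_len(nrow(cond))) {
    for (r in seq_len(config$duplicates_per_condition)) {
      slice_id <- sprintf("%s_%s_s%d", culture, cond$condition[i], r)
      vf <- perturb_fraction(expected[i, "viable_frac"], config$noise_sd)
      rec <- if (mode == "outgrowth") {
        of <- perturb_fraction(expected[i, "outgrowth_frac"], config$noise_sd)
        perim <- config$perimeter_mean_um * stats::runif(1, 0.8, 1.2)
        out_len <- of * perim
        viable_len <- vf * out_len
        damaged_len <- (1 - vf) * out_len
        data.frame(
          annotation_class = c("perimeter", viable_class_names, damaged_class_names),
          measure_kind = c("perimeter", rep("length", 6)),
          value = c(perim,
                    viable_len * random_composition(4),
                    damaged_len * random_composition(2)),
          unit = "um",
          stringsAsFactors = FALSE
        )
      } else {
        area <- 2e6 * stats::runif(1, 0.8, 1.2)
        data.frame(
          annotation_class = c("tumor_viable_area", "tumor_damaged_area"),
          measure_kind = "area",
          value = c(vf * area, (1 - vf) * area),
          unit = "um2",
          stringsAsFactors = FALSE
        )
      }
      rec <- cbind(
        data.frame(culture_id = culture, slice_id = slice_id, replicate = r,
                   condition = cond$condition[i], dose_um = cond$dose_um[i],
                   stringsAsFactors = FALSE),
        rec
      )
      rows[[length(rows) + 1L]] <- rec
    }
  }
  list(annotations = do.call(rbind, rows), truth = truth)
}

#' Generate a synthetic differential-expression results table
#'
#' Null genes carry uniform p-values and near-zero log2 fold changes; signal
#' genes carry |log2FC| >= `effect_log2fc` and p-values below 1e-5. Aligned
#' read counts follow a lognormal distribution calibrated so that a fraction
#' `low_read_frac` of genes falls below 350 reads in expectation. Adjusted
#' p-values are Benjamini-Hochberg over the whole table.
#'
#' @param n_genes total number of genes.
#' @param n_signal number of true-signal genes (<= `n_genes`).
#' @param effect_log2fc minimum absolute log2 fold change of signal genes.
#' @param seed integer seed.
#' @param low_read_frac expected fraction of genes with fewer than 350 reads.
#' @param reads_sdlog lognormal sdlog of the read-count distribution.
#' @return data.frame with columns `gene_id`, `total_reads`, `log2fc`,
#'   `p_value`, `p_adjusted`.
#' @export
generate_de_table <- function(n_genes, n_signal = 0, effect_log2fc = 2,
                              seed = 1L, low_read_frac = 0.3,
                              reads_sdlog = 1.5) {
  if (n_genes < 0 || n_signal < 0) stop("gene counts must be non-negative")
  if (n_signal > n_genes) stop("n_signal must be <= n_genes")
  if (low_read_frac < 0 || low_read_frac >= 1)
    stop("low_read_frac must be in [0, 1)")
  local_seed(as.integer(seed), {
    meanlog <- log(350) - reads_sdlog * stats::qnorm(low_read_frac)
    reads <- round(stats::rlnorm(n_genes, meanlog, reads_sdlog))
    is_signal <- seq_len(n_genes) <= n_signal
    p <- stats::runif(n_genes)
    p[is_signal] <- 10^stats::runif(n_signal, -10, -5)
    lfc <- stats::rnorm(n_genes, 0, 0.15)
    lfc[is_signal] <- sample(c(-1, 1), n_signal, replace = TRUE) *
      effect_log2fc * (1 + stats::rexp(n_signal, rate = 5))
    data.frame(
      gene_id = sprintf("G%05d", seq_len(max(n_genes, 0))),
      total_reads = reads,
      log2fc = lfc,
      p_value = p,
      p_adjusted = stats::p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE
    )
  })
}
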