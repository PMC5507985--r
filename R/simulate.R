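# Ground-truth simulator for the two degradation experiment designs:
#  (a) a 3-tissue x 2-temperature x 8-time-point cold-ischemia time course
#      (one array per condition, 48 samples), and
#  (b) a liver control experiment: intact/degraded tissue RNA with and
#      without DNase digestion plus small-RNA-depleted RNA treated with
#      RNase doses, 8 conditions x 3 replicates = 24 samples.
# Each simulated miRNA carries a latent class (degradation-resilient,
# degradation-sensitive, cross-hybridization artifact, DNA background) so
# every downstream screen can be checked against known truth.

#' RIN decay model for one tissue/temperature condition
#'
#' Three empirical shapes of RNA-integrity decline during cold ischemia are
#' supported: \code{linear} (RIN = 10 - slope * t), \code{two_phase} (a
#' plateau at RIN 10 for \code{plateau_h} hours followed by linear decline)
#' and \code{hyperbolic} (RIN = 1 + 9 / (1 + t / tau)). Predictions are
#' clamped to [1, 10] and are non-increasing in time when noise is off.
#'
#' @param tissue One of liver/heart/brain.
#' @param temperature "4C" or "RT".
#' @param shape Decay shape: "linear", "two_phase" or "hyperbolic".
#' @param slope RIN units lost per hour (linear and two_phase).
#' @param plateau_h Plateau length in hours (two_phase).
#' @param tau Half-decay time scale in hours (hyperbolic).
#' @param noise_sd Standard deviation of Gaussian RIN noise (RIN units).
#' @return An object of class \code{decay_model}.
#' @examples
#' m <- decay_model("liver", "RT", "hyperbolic", tau = 3)
#' simulate_rin(m, 6, noise_sd = 0)  # 4
#' @export
decay_model <- function(tissue, temperature,
                        shape = c("linear", "two_phase", "hyperbolic"),
                        slope = 0.05, plateau_h = 24, tau = 3, noise_sd = 0.25) {
  shape <- match.arg(shape)
  match_enum(tissue, c("liver", "heart", "brain"), "tissue")
  match_enum(temperature, c("4C", "RT"), "temperature")
  if (slope < 0 || plateau_h < 0 || tau <= 0 || noise_sd < 0) {
    fail("decay model parameters must be non-negative (tau strictly positive)")
  }
  structure(list(tissue = tissue, temperature = temperature, shape = shape,
                 slope = slope, plateau_h = plateau_h, tau = tau,
                 noise_sd = noise_sd),
            class = "decay_model")
}

#' Default decay models for the six tissue/temperature conditions
#'
#' Encodes the observed qualitative kinetics: at 4C all tissues decay
#' linearly and slowly (brain and heart keep RIN above 7 through 96 h); at
#' room temperature brain declines linearly, heart shows a two-phase course
#' with a 24 h plateau, and liver decays hyperbolically, reaching RIN 4
#' after 6 h.
#'
#' @param noise_sd RIN noise applied to every model (default 0.25).
#' @return Named list of six \code{\link{decay_model}} objects, keyed
#'   \code{"<tissue>_<temperature>"}.
#' @export
default_decay_models <- function(noise_sd = 0.25) {
  list(
    liver_RT = decay_model("liver", "RT", "hyperbolic", tau = 3, noise_sd = noise_sd),
    heart_RT = decay_model("heart", "RT", "two_phase", slope = 0.1, plateau_h = 24,
                           noise_sd = noise_sd),
    brain_RT = decay_model("brain", "RT", "linear", slope = 0.0625, noise_sd = noise_sd),
    liver_4C = decay_model("liver", "4C", "linear", slope = 0.05, noise_sd = noise_sd),
    heart_4C = decay_model("heart", "4C", "linear", slope = 0.025, noise_sd = noise_sd),
    brain_4C = decay_model("brain", "4C", "linear", slope = 0.02, noise_sd = noise_sd)
  )
}

#' Simulate a RIN value under a decay model
#'
#' @param model A \code{\link{decay_model}}.
#' @param time_h Storage time(s) in hours, non-negative.
#' @param noise_sd Overrides the model's RIN noise SD; 0 gives the
#'   deterministic decay curve.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return RIN value(s) in [1, 10].
#' @export
simulate_rin <- function(model, time_h, noise_sd = model$noise_sd, seed = NULL) {
  if (!inherits(model, "decay_model")) fail("model must be a decay_model")
  if (any(time_h < 0)) fail("storage time must be non-negative")
  base <- switch(model$shape,
    linear = 10 - model$slope * time_h,
    two_phase = 10 - model$slope * pmax(0, time_h - model$plateau_h),
    hyperbolic = 1 + 9 / (1 + time_h / model$tau)
  )
  out <- with_seed(seed, base + if (noise_sd > 0)
    stats::rnorm(length(time_h), 0, noise_sd) else 0)
  pmin(10, pmax(1, out))
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the simulator emulates: 900 miRNAs
#' in four latent classes with log2 effects expressed as the signed change
#' from fully intact (degradation index D = 0) to fully degraded (D = 1)
#' RNA, log2 measurement noise of 0.5, and a miRBase-version mixture that
#' ties artifact-like classes to recent (NGS-era) versions.
#'
#' @param n_resilient,n_sensitive,n_artifact,n_dna_background Class sizes
#'   (defaults 300/200/300/100).
#' @param effect_sensitive,effect_artifact,effect_dna Uniform log2 effect
#'   ranges per class (defaults U[-4,-1.5], U[1.5,4], U[1.5,3]).
#' @param baseline_genuine,baseline_artifact Uniform log2 baseline ranges for
#'   genuine (resilient/sensitive) and artifact-like (artifact/DNA
#'   background) miRNAs. Artifact-like baselines sit just above the
#'   detection threshold so their signals are measurable in intact samples
#'   but their detected counts rise with degradation.
#' @param noise_sd_log2 SD of per-cell log2 measurement noise (default 0.5).
#' @param tissue_sd_log2 SD of per-miRNA, per-tissue baseline offsets
#'   (default 0, i.e. the plain signal model
#'   \code{baseline + effect * D + noise}); positive values give intact
#'   samples tissue-specific profiles at the cost of extra
#'   RIN-uncorrelated variance.
#' @param detect_log2 Detection threshold on the log2 signal (default 5):
#'   a probe is flagged detected when its signal reaches this level.
#' @param depletion_log2 log2 signal drop of small RNAs in the depleted RNA
#'   fraction (default 8), placing genuine miRNAs below detection there.
#' @param p_recent_artifact Probability that an artifact-like miRNA draws its
#'   first miRBase version from 16..21 (default 0.85, else 1..15).
#' @param p_early_genuine Probability that a genuine miRNA draws its first
#'   version from 1..9 (default 0.8, else 10..21).
#' @param seed Default seed for the simulator functions.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_resilient = 300L, n_sensitive = 200L,
                       n_artifact = 300L, n_dna_background = 100L,
                       effect_sensitive = c(-4, -1.5),
                       effect_artifact = c(1.5, 4),
                       effect_dna = c(1.5, 3),
                       baseline_genuine = c(7, 12),
                       baseline_artifact = c(5.5, 7),
                       noise_sd_log2 = 0.5,
                       tissue_sd_log2 = 0,
                       detect_log2 = 5,
                       depletion_log2 = 8,
                       p_recent_artifact = 0.85,
                       p_early_genuine = 0.8,
                       seed = 1L) {
  n <- c(n_resilient, n_sensitive, n_artifact, n_dna_background)
  if (any(n < 0)) fail("class counts must be >= 0")
  if (sum(n) == 0L) fail("at least one miRNA class must be non-empty")
  if (any(effect_sensitive >= 0)) fail("sensitive effects must be negative")
  if (any(effect_artifact <= 0) || any(effect_dna <= 0)) {
    fail("artifact and dna_background effects must be positive")
  }
  for (p in c(p_recent_artifact, p_early_genuine)) {
    if (p < 0 || p > 1) fail("version mixture probabilities must lie in [0,1]")
  }
  if (noise_sd_log2 < 0 || tissue_sd_log2 < 0) fail("noise SDs must be >= 0")
  structure(list(
    n_resilient = as.integer(n_resilient), n_sensitive = as.integer(n_sensitive),
    n_artifact = as.integer(n_artifact), n_dna_background = as.integer(n_dna_background),
    effect_sensitive = effect_sensitive, effect_artifact = effect_artifact,
    effect_dna = effect_dna,
    baseline_genuine = baseline_genuine, baseline_artifact = baseline_artifact,
    noise_sd_log2 = noise_sd_log2, tissue_sd_log2 = tissue_sd_log2,
    detect_log2 = detect_log2, depletion_log2 = depletion_log2,
    p_recent_artifact = p_recent_artifact, p_early_genuine = p_early_genuine,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw the latent per-miRNA ground truth
#'
#' Samples each simulated miRNA's class, log2 baseline, log2 effect, first
#' miRBase version and a random mature sequence (20-23 nt).
#'
#' @param sim A \code{\link{sim_config}}.
#' @param seed Integer seed (default \code{sim$seed}).
#' @return Data.frame with columns \code{mirna_id}, \code{klass},
#'   \code{baseline_log2}, \code{effect_log2}, \code{first_version},
#'   \code{mature_sequence}.
#' @export
simulate_truth <- function(sim = sim_config(), seed = sim$seed) {
  klass <- rep(c("resilient", "sensitive", "artifact", "dna_background"),
               c(sim$n_resilient, sim$n_sensitive, sim$n_artifact, sim$n_dna_background))
  n <- length(klass)
  with_seed(seed, {
    runifr <- function(n, r) stats::runif(n, r[1], r[2])
    baseline <- ifelse(klass %in% c("resilient", "sensitive"),
                       runifr(n, sim$baseline_genuine),
                       runifr(n, sim$baseline_artifact))
    effect <- numeric(n)
    effect[klass == "sensitive"] <- runifr(sum(klass == "sensitive"), sim$effect_sensitive)
    effect[klass == "artifact"] <- runifr(sum(klass == "artifact"), sim$effect_artifact)
    effect[klass == "dna_background"] <- runifr(sum(klass == "dna_background"), sim$effect_dna)
    recent <- stats::runif(n) < ifelse(klass %in% c("resilient", "sensitive"),
                                       1 - sim$p_early_genuine, sim$p_recent_artifact)
    version <- integer(n)
    genuine <- klass %in% c("resilient", "sensitive")
    version[genuine & !recent] <- sample(1:9, sum(genuine & !recent), replace = TRUE)
    version[genuine & recent] <- sample(10:21, sum(genuine & recent), replace = TRUE)
    version[!genuine & recent] <- sample(16:21, sum(!genuine & recent), replace = TRUE)
    version[!genuine & !recent] <- sample(1:15, sum(!genuine & !recent), replace = TRUE)
    seqs <- random_unique_sequences(n, 20:23)
    data.frame(
      mirna_id = sprintf("sim-miR-%04d", seq_len(n)),
      klass = klass,
      baseline_log2 = baseline,
      effect_log2 = effect,
      first_version = version,
      mature_sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
}

random_unique_sequences <- function(n, lengths) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- if (length(lengths) == 1L) rep(lengths, need) else
      sample(lengths, need, replace = TRUE)
    fresh <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

truth_annotation <- function(truth) {
  validate_mirbase_annotation(truth[, c("mirna_id", "mature_sequence", "first_version")])
}

# signal -> ExpressionMatrix on the raw intensity scale
signal_to_matrix <- function(log2_signal, detect_log2) {
  expression_matrix(2^log2_signal, log2_signal >= detect_log2, state = "raw")
}

#' Simulate the tissue/temperature time-course experiment
#'
#' Generates 48 samples (3 tissues x 2 temperatures x 8 storage times: 0, 1,
#' 3, 6, 14, 24, 48, 96 h). Sample RIN follows the decay models; each
#' miRNA's log2 signal is \code{baseline + tissue offset + effect * D +
#' noise} where the degradation index \code{D = (10 - RIN) / 9} maps RIN
#' linearly onto [0, 1]. Raw intensities are \code{2^signal}; a cell is
#' flagged detected when its log2 signal reaches the detection threshold.
#'
#' @param sim A \code{\link{sim_config}}.
#' @param decay_models Named list of decay models covering all six
#'   tissue/temperature pairs (see \code{\link{default_decay_models}}).
#' @param truth Optional pre-drawn truth table (so the control experiment can
#'   share the same miRNAs); drawn with \code{\link{simulate_truth}} when
#'   \code{NULL}.
#' @param seed Integer seed (default \code{sim$seed}).
#' @return List with \code{expression} (raw \code{ExpressionMatrix}),
#'   \code{meta} (48-row sample metadata), \code{annotation}, \code{truth}.
#' @export
simulate_timecourse <- function(sim = sim_config(),
                                decay_models = default_decay_models(),
                                truth = NULL, seed = sim$seed) {
  tissues <- c("liver", "heart", "brain")
  temps <- c("4C", "RT")
  times <- c(0, 1, 3, 6, 14, 24, 48, 96)
  for (ti in tissues) for (te in temps) {
    key <- paste(ti, te, sep = "_")
    if (is.null(decay_models[[key]])) fail("missing decay model for %s", key)
  }
  if (is.null(truth)) truth <- simulate_truth(sim, seed = seed)
  n <- nrow(truth)
  design <- expand.grid(time_h = times, tissue = tissues, temperature = temps,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%gh", design$temperature, design$tissue,
                              design$time_h)
  with_seed(seed + 1L, {
    rin <- vapply(seq_len(nrow(design)), function(i) {
      m <- decay_models[[paste(design$tissue[i], design$temperature[i], sep = "_")]]
      simulate_rin(m, design$time_h[i])
    }, numeric(1))
    tissue_off <- matrix(stats::rnorm(n * length(tissues), 0, sim$tissue_sd_log2),
                         n, length(tissues), dimnames = list(truth$mirna_id, tissues))
    D <- (10 - rin) / 9
    signal <- outer(truth$baseline_log2, rep(1, nrow(design))) +
      tissue_off[, design$tissue] +
      outer(truth$effect_log2, D) +
      matrix(stats::rnorm(n * nrow(design), 0, sim$noise_sd_log2), n, nrow(design))
    dimnames(signal) <- list(truth$mirna_id, design$sample_id)
    meta <- data.frame(
      sample_id = design$sample_id, tissue = design$tissue,
      temperature = design$temperature, time_h = design$time_h,
      rin = round(rin, 2), replicate = 1L, arm = "timecourse",
      rna_fraction = "with_small_rna", dnase = "na", rnase_units = "na",
      stringsAsFactors = FALSE
    )
    list(expression = signal_to_matrix(signal, sim$detect_log2),
         meta = validate_sample_meta(meta),
         annotation = truth_annotation(truth),
         truth = truth)
  })
}

control_design <- function() {
  d <- rbind(
    data.frame(cond = "intact_dnase",      time_h = 0,  rna_fraction = "with_small_rna", dnase = "yes", rnase_units = "na",    rin0 = 9.8),
    data.frame(cond = "intact_nodnase",    time_h = 0,  rna_fraction = "with_small_rna", dnase = "no",  rnase_units = "na",    rin0 = 9.8),
    data.frame(cond = "degraded_dnase",    time_h = 96, rna_fraction = "with_small_rna", dnase = "yes", rnase_units = "na",    rin0 = 1.5),
    data.frame(cond = "degraded_nodnase",  time_h = 96, rna_fraction = "with_small_rna", dnase = "no",  rnase_units = "na",    rin0 = 1.5),
    data.frame(cond = "depleted_0u_dnase", time_h = 0,  rna_fraction = "depleted",       dnase = "yes", rnase_units = "0",     rin0 = 9.5),
    data.frame(cond = "depleted_0u_nodnase", time_h = 0, rna_fraction = "depleted",      dnase = "no",  rnase_units = "0",     rin0 = 9.5),
    data.frame(cond = "depleted_lowrnase", time_h = 0,  rna_fraction = "depleted",       dnase = "yes", rnase_units = "0.027", rin0 = 5),
    data.frame(cond = "depleted_highrnase", time_h = 0, rna_fraction = "depleted",       dnase = "yes", rnase_units = "0.67",  rin0 = 2)
  )
  d
}

#' Simulate the control (confounder) experiment
#'
#' Generates the liver control design probing the sources of
#' degradation-associated signals: 8 conditions x 3 replicates = 24 samples
#' covering intact and 96 h room-temperature degraded tissue RNA (each with
#' and without DNase digestion), small-RNA-depleted RNA with and without
#' DNase at 0 U RNase, and depleted RNA fragmented with 0.027 U or 0.67 U
#' RNase. Noise-free log2 signal rules per latent class:
#' \itemize{
#'   \item resilient: baseline in all small-RNA arms; baseline minus the
#'     depletion drop in every depleted arm.
#'   \item sensitive: as resilient, but baseline + effect (effect < 0) in the
#'     degraded small-RNA arms.
#'   \item artifact: baseline + effect in degraded small-RNA arms and in the
#'     RNase-fragmented depleted arms (half effect at the low dose, full at
#'     the high dose); baseline minus depletion at 0 U.
#'   \item dna_background: baseline + effect only in the degraded, DNase-free
#'     small-RNA arm.
#' }
#'
#' @inheritParams simulate_timecourse
#' @return List with \code{expression}, \code{meta}, \code{annotation},
#'   \code{truth}.
#' @export
simulate_control_experiment <- function(sim = sim_config(), truth = NULL,
                                        seed = sim$seed) {
  if (is.null(truth)) truth <- simulate_truth(sim, seed = seed)
  n <- nrow(truth)
  des <- control_design()
  des <- des[rep(seq_len(nrow(des)), each = 3L), ]
  des$replicate <- rep(1:3, times = 8L)
  des$sample_id <- sprintf("ctrl_%s_r%d", des$cond, des$replicate)
  b <- truth$baseline_log2
  e <- truth$effect_log2
  dep <- sim$depletion_log2
  signal_for <- function(row) {
    if (row$rna_fraction == "with_small_rna") {
      if (row$time_h == 0) return(b)
      s <- b
      s[truth$klass == "sensitive"] <- (b + e)[truth$klass == "sensitive"]
      s[truth$klass == "artifact"] <- (b + e)[truth$klass == "artifact"]
      if (row$dnase == "no") {
        s[truth$klass == "dna_background"] <- (b + e)[truth$klass == "dna_background"]
      }
      return(s)
    }
    # depleted fraction: small RNAs removed; RNase fragments re-create
    # artifact-class signals dose-dependently
    s <- b - dep
    if (row$rnase_units == "0.027") s[truth$klass == "artifact"] <- (b + e / 2)[truth$klass == "artifact"]
    if (row$rnase_units == "0.67") s[truth$klass == "artifact"] <- (b + e)[truth$klass == "artifact"]
    s
  }
  with_seed(seed + 2L, {
    signal <- vapply(seq_len(nrow(des)), function(i) signal_for(des[i, ]), numeric(n))
    signal <- signal + matrix(stats::rnorm(n * nrow(des), 0, sim$noise_sd_log2),
                              n, nrow(des))
    dimnames(signal) <- list(truth$mirna_id, des$sample_id)
    rin <- pmin(10, pmax(1, des$rin0 + stats::rnorm(nrow(des), 0, 0.15)))
    meta <- data.frame(
      sample_id = des$sample_id, tissue = "liver", temperature = "RT",
      time_h = des$time_h, rin = round(rin, 2), replicate = des$replicate,
      arm = "control", rna_fraction = des$rna_fraction, dnase = des$dnase,
      rnase_units = des$rnase_units, stringsAsFactors = FALSE
    )
    list(expression = signal_to_matrix(signal, sim$detect_log2),
         meta = validate_sample_meta(meta),
         annotation = truth_annotation(truth),
         truth = truth)
  })
}

#' Simulate a transcript set carrying planted miRNA homologies
#'
#' Builds synthetic mRNA-like transcripts in which the mature sequences of
#' the requested miRNAs (typically the artifact class, whose array signals
#' are explained by cross-hybridizing transcript fragments) are embedded as
#' exact substrings; the remaining transcripts are random background.
#'
#' @param annotation Annotation table with \code{mirna_id} and
#'   \code{mature_sequence}.
#' @param embed_ids miRNA IDs to embed (default none).
#' @param per_transcript How many miRNA sequences to plant per transcript
#'   (default 4).
#' @param n_background Number of random transcripts without planted
#'   homology (default 25).
#' @param length Transcript length in nt (default 500).
#' @param seed Integer seed.
#' @return Named character vector of transcript sequences.
#' @export
simulate_transcripts <- function(annotation, embed_ids = character(0),
                                 per_transcript = 4L, n_background = 25L,
                                 length = 500L, seed = 1L) {
  annotation <- validate_mirbase_annotation(annotation)
  missing_ids <- setdiff(embed_ids, annotation$mirna_id)
  if (length(missing_ids)) {
    fail("embed_ids not in annotation: %s", paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  # decorrelate from the truth-table stream even when the same seed is passed:
  # background transcripts drawn from the identical RNG state would otherwise
  # replay the mature-sequence letter draws and create spurious homology
  seed <- as.integer((as.double(seed) * 1103515245 + 12345) %% 2147483647)
  with_seed(seed, {
    seqs <- annotation$mature_sequence[match(embed_ids, annotation$mirna_id)]
    groups <- if (length(seqs)) split(seqs, ceiling(seq_along(seqs) / per_transcript)) else list()
    n_tx <- length(groups) + n_background
    tx <- random_unique_sequences(n_tx, length)
    slot_w <- if (per_transcript > 0) length %/% per_transcript else length
    for (g in seq_along(groups)) {
      s <- tx[g]
      for (j in seq_along(groups[[g]])) {
        mir <- groups[[g]][j]
        lo <- (j - 1L) * slot_w + 1L
        start <- lo + sample.int(max(1L, slot_w - nchar(mir) - 1L), 1L) - 1L
        substr(s, start, start + nchar(mir) - 1L) <- mir
      }
      tx[g] <- s
    }
    stats::setNames(tx, sprintf("tx%04d", seq_len(n_tx)))
  })
}
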