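# Seeded synthetic generator of MD-like pharmacophore ensembles and matched
# screening libraries. Each feature follows a two-state Markov chain whose
# stationary on-probability is exactly the requested p; the persistence
# parameter rho controls frame-to-frame autocorrelation (rho = 0 gives iid
# frames). Optional latent binding modes switch the per-feature
# probabilities, producing the multi-branch graphs seen with proteins that
# accommodate distinct ligand poses.

#' Trajectory simulation parameters
#'
#' @param features Data frame with columns `feature` (canonical serials),
#'   `p` (stationary on-probability in (0, 1)) and optionally `rho`
#'   (persistence in `[0, 1)`, default 0.6 — MD frames are autocorrelated).
#' @param n_frames Number of frames to simulate.
#' @param modes Optional named list of binding modes; each element is a
#'   numeric vector of per-feature stationary probabilities (same length
#'   and order as `features`). When given, a latent mode sequence is
#'   simulated and each frame uses its current mode's probabilities.
#' @param switch_prob Per-frame probability of leaving the current mode.
#' @param system_id,run_id Provenance attached to the generated models.
#' @param seed Integer seed; the whole trajectory is deterministic given it.
#' @return A `hgpm_trajectory_params` list.
#' @export
trajectory_params <- function(features, n_frames = 500L, modes = NULL,
                              switch_prob = 0.01, system_id = "sim",
                              run_id = "run1", seed = 1L) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L,
            all(c("feature", "p") %in% names(features)))
  if (is.null(features$rho)) features$rho <- 0.6
  if (any(features$p <= 0 | features$p >= 1)) {
    hgpm_stop("hgpm_parameter_error", "stationary probabilities must lie in (0, 1)")
  }
  if (any(features$rho < 0 | features$rho >= 1)) {
    hgpm_stop("hgpm_parameter_error", "persistence must lie in [0, 1)")
  }
  if (!is.null(modes)) {
    ok <- all(vapply(modes, function(m) length(m) == nrow(features) &&
                       all(m > 0 & m < 1), logical(1)))
    if (!ok) {
      hgpm_stop("hgpm_parameter_error",
                "each mode needs one probability in (0,1) per feature")
    }
    if (switch_prob < 0 || switch_prob > 1) {
      hgpm_stop("hgpm_parameter_error", "switch_prob must lie in [0, 1]")
    }
  }
  structure(list(features = features, n_frames = as.integer(n_frames),
                 modes = modes, switch_prob = switch_prob,
                 system_id = system_id, run_id = run_id,
                 seed = as.integer(seed)),
            class = "hgpm_trajectory_params")
}

#' Simulate an MD-like pharmacophore ensemble
#'
#' Per feature, a two-state Markov chain with `P(on -> on) = p + rho(1-p)`,
#' `P(off -> on) = p(1-rho)` and initial state `Bernoulli(p)`, so the
#' stationary marginal is exactly `p`. Frame t's pharmacophore model is the
#' set of features that are "on" at t. With binding modes, a latent Markov
#' mode sequence selects which per-feature `p` applies at each frame.
#'
#' @param params A [trajectory_params()] object.
#' @return List of [pharmacophore_model()] objects, one per frame
#'   (0-based `frame_index`); attribute `mode_sequence` carries the latent
#'   mode per frame when modes were simulated.
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "hgpm_trajectory_params"))
  ft <- params$features
  nf <- params$n_frames
  k <- nrow(ft)
  withr_seed <- params$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  mode_seq <- NULL
  if (!is.null(params$modes)) {
    nm <- length(params$modes)
    mode_seq <- integer(nf)
    mode_seq[1L] <- sample.int(nm, 1L)
    if (nf > 1L) {
      for (t in 2:nf) {
        if (nm > 1L && stats::runif(1) < params$switch_prob) {
          others <- setdiff(seq_len(nm), mode_seq[t - 1L])
          mode_seq[t] <- others[sample.int(length(others), 1L)]
        } else {
          mode_seq[t] <- mode_seq[t - 1L]
        }
      }
    }
    p_mat <- matrix(unlist(params$modes), nrow = k)  # features x modes
  }

  states <- matrix(FALSE, nf, k)
  for (j in seq_len(k)) {
    rho <- ft$rho[j]
    p_t <- if (is.null(mode_seq)) rep(ft$p[j], nf) else p_mat[j, mode_seq]
    u <- stats::runif(nf)
    states[1L, j] <- u[1L] < p_t[1L]
    if (nf > 1L) {
      for (t in 2:nf) {
        pr <- if (states[t - 1L, j]) p_t[t] + rho * (1 - p_t[t]) else p_t[t] * (1 - rho)
        states[t, j] <- u[t] < pr
      }
    }
  }

  models <- lapply(seq_len(nf), function(t) {
    pharmacophore_model(params$system_id, params$run_id, t - 1L,
                        ft$feature[states[t, ]], mode = "ligand_aware")
  })
  attr(models, "mode_sequence") <- mode_seq
  attr(models, "states") <- states
  models
}

#' Default glucokinase-like feature table
#'
#' A realistic small interaction alphabet for a kinase activator site:
#' three persistent polar anchors to the ARG63/SER64 backbone region (the
#' "core"), plus hydrophobic, aromatic and halogen-bond features of varying
#' stability elsewhere in the pocket.
#'
#' @return Data frame with columns `feature`, `p`, `rho`, `core`.
#' @export
example_feature_table <- function() {
  data.frame(
    feature = c("HBA|N1|ARG63", "HBD|N2|ARG63", "HBA|O1|SER64",
                "H|C7|ILE211,TYR214", "H|F1|ILE211,TYR214,TYR215",
                "AR|C1,C2,C3,C4,C5,C6|TYR214", "H|C9|MET210,THR65",
                "HBA|O2|THR65", "XBD|CL1|TYR24"),
    p = c(0.92, 0.90, 0.85, 0.55, 0.35, 0.30, 0.20, 0.15, 0.05),
    rho = c(0.6, 0.6, 0.6, 0.6, 0.5, 0.5, 0.4, 0.4, 0.3),
    core = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Two example binding modes for the glucokinase-like feature table
#'
#' Emulates a protein that accommodates two distinct ligand poses: both
#' modes keep the polar core anchored, but each stabilises a disjoint set
#' of extension features (mode 1 the ILE211/TYR214 hydrophobics, mode 2
#' the aromatic stacking and the MET210/THR65 contact). Trajectories run
#' with these modes yield graphs with two specialized branches.
#'
#' @param features Feature table from [example_feature_table()].
#' @return Named list of per-feature stationary probabilities.
#' @export
example_binding_modes <- function(features = example_feature_table()) {
  p1 <- features$p
  p2 <- features$p
  ext1 <- features$feature %in% c("H|C7|ILE211,TYR214",
                                  "H|F1|ILE211,TYR214,TYR215")
  ext2 <- features$feature %in% c("AR|C1,C2,C3,C4,C5,C6|TYR214",
                                  "H|C9|MET210,THR65")
  p1[ext1] <- 0.85; p1[ext2] <- 0.02
  p2[ext1] <- 0.02; p2[ext2] <- 0.85
  list(mode1 = p1, mode2 = p2)
}

#' Screening-library simulation parameters
#'
#' @param n_actives,n_decoys Library composition.
#' @param core Character vector of feature serials forming the
#'   pharmacophoric core that active molecules tend to satisfy.
#' @param active_core_prob Probability that an active contains the full
#'   core (default 0.9: potent binders almost always satisfy the anchoring
#'   interactions).
#' @param active_noise_prob Per-feature probability of each non-core
#'   feature in an active (default 0.5: binders realize roughly half of
#'   the peripheral contacts, which is what makes consensus scores of
#'   actives high).
#' @param decoy_feature_prob Per-feature probability in a decoy
#'   (default 0.1: decoys rarely realize any given contact); 0 makes
#'   decoys featureless.
#' @param seed Integer seed.
#' @return A `hgpm_library_params` list.
#' @export
library_params <- function(n_actives = 60L, n_decoys = 240L, core,
                           active_core_prob = 0.9, active_noise_prob = 0.5,
                           decoy_feature_prob = 0.1, seed = 1L) {
  if (n_actives < 1L || n_decoys < 1L) {
    hgpm_stop("hgpm_parameter_error", "n_actives and n_decoys must be positive")
  }
  for (p in c(active_core_prob, active_noise_prob, decoy_feature_prob)) {
    if (p < 0 || p > 1) hgpm_stop("hgpm_parameter_error", "probabilities must lie in [0, 1]")
  }
  structure(list(n_actives = as.integer(n_actives), n_decoys = as.integer(n_decoys),
                 core = core, active_core_prob = active_core_prob,
                 active_noise_prob = active_noise_prob,
                 decoy_feature_prob = decoy_feature_prob, seed = as.integer(seed)),
            class = "hgpm_library_params")
}

#' Simulate a matched screening library
#'
#' Actives are generated as supersets of the pharmacophoric core (with
#' probability `active_core_prob`) plus per-feature noise; decoys are
#' sparse random feature sets. Molecules are abstract feature sets over the
#' same universe as the trajectory, so the stub screen below can act on
#' them exactly like a 3D screen acts on conformers.
#'
#' @param params A [library_params()] object.
#' @param universe An `hgpm_catalog` (or character vector) of all features.
#' @return List with `molecules` (named list of feature-serial sets) and
#'   `labels` (named `"active"`/`"decoy"` vector); attribute `report`
#'   records the realized core-coverage rates.
#' @export
simulate_library <- function(params, universe) {
  stopifnot(inherits(params, "hgpm_library_params"))
  feats <- if (inherits(universe, "hgpm_catalog")) universe$entries else as.character(universe)
  if (!all(params$core %in% feats)) {
    hgpm_stop("hgpm_parameter_error", "core features must be part of the universe")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)
  noncore <- setdiff(feats, params$core)
  actives <- lapply(seq_len(params$n_actives), function(i) {
    base <- if (stats::runif(1) < params$active_core_prob) params$core else character(0)
    noise <- noncore[stats::runif(length(noncore)) < params$active_noise_prob]
    sort_c(unique(c(base, noise)))
  })
  decoys <- lapply(seq_len(params$n_decoys), function(i) {
    sort_c(feats[stats::runif(length(feats)) < params$decoy_feature_prob])
  })
  molecules <- c(actives, decoys)
  names(molecules) <- c(sprintf("act_%04d", seq_len(params$n_actives)),
                        sprintf("dec_%04d", seq_len(params$n_decoys)))
  labels <- c(rep("active", params$n_actives), rep("decoy", params$n_decoys))
  names(labels) <- names(molecules)
  covers <- function(m) length(params$core) > 0L && all(params$core %in% m)
  report <- list(active_core_coverage = mean(vapply(actives, covers, logical(1))),
                 decoy_core_coverage = mean(vapply(decoys, covers, logical(1))),
                 seed = params$seed)
  out <- list(molecules = molecules, labels = labels)
  attr(out, "report") <- report
  out
}

#' Feature-subset screening stub
#'
#' Stand-in for a 3D pharmacophore screen on abstract feature sets: a
#' molecule is a hit for a model iff the model's features are a subset of
#' the molecule's, and the model has at least 3 features — smaller models
#' cannot be unambiguously aligned in 3D space and return no hits.
#'
#' @param model Character vector of feature serials (the query model).
#' @param molecule Character vector of feature serials (the molecule).
#' @return Logical hit indicator.
#' @export
screening_stub <- function(model, molecule) {
  length(model) >= 3L && all(model %in% molecule)
}

#' Screen a library with a set of models
#'
#' Applies [screening_stub()] to every (model, molecule) pair and returns a
#' hit table ready for [consensus_score()] and [truncated_roc_auc()].
#'
#' @param models Named list of feature-serial sets (one per model id).
#' @param library Output of [simulate_library()], or a list with
#'   `molecules` and `labels`.
#' @return Hit-table data frame (`molecule_id`, `label`, `model_id`, `hit`).
#' @export
screen_library <- function(models, library) {
  stopifnot(!is.null(names(models)), length(models) > 0L)
  mols <- library$molecules
  labs <- library$labels
  rows <- lapply(names(models), function(mid) {
    hits <- vapply(mols, function(mol) screening_stub(models[[mid]], mol),
                   logical(1))
    data.frame(molecule_id = names(mols), label = unname(labs[names(mols)]),
               model_id = mid, hit = as.integer(hits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
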