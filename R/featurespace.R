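# Feature identity and feature-vector construction.
#
# A pharmacophore feature is identified by its interaction type, the ligand
# atoms it involves, and the protein residues it interacts with; 3D placement
# is deliberately ignored. Two "modes" exist: ligand_aware keys keep the
# ligand atoms, projected keys drop them so that ensembles obtained with
# different ligands of the same protein become comparable.

#' Interaction-type vocabulary
#'
#' The seven chemical feature types recognised by the package: hydrophobic
#' (`H`), aromatic ring (`AR`), hydrogen-bond acceptor (`HBA`), hydrogen-bond
#' donor (`HBD`), positive ionizable (`PI`), negative ionizable (`NI`) and
#' halogen-bond donor (`XBD`).
#'
#' @return Character vector of the seven type codes.
#' @export
feature_types <- function() {
  c("H", "AR", "HBA", "HBD", "PI", "NI", "XBD")
}

check_identifiers <- function(x, what) {
  if (!is.character(x)) hgpm_stop("hgpm_invalid_feature", "%s must be character", what)
  bad <- !nzchar(x) | grepl("[|,]", x)
  if (any(bad)) {
    hgpm_stop("hgpm_invalid_feature",
              "invalid %s identifier(s): %s (must be non-empty, without '|' or ',')",
              what, paste(x[bad], collapse = ", "))
  }
  invisible(x)
}

#' Create a canonical pharmacophore feature key
#'
#' Builds the canonical identity of a unique pharmacophore feature from its
#' interaction type, the ligand atoms involved and the interacting protein
#' residues. Identifier lists are sorted and deduplicated so that equal
#' features always serialize to the same string. In `projected` mode the
#' ligand atoms are discarded: only the interaction type and the protein-side
#' residues remain, which merges features that differ only in where they
#' touch the ligand.
#'
#' @param feature_type One of [feature_types()].
#' @param ligand_atoms Character vector of ligand atom identifiers. Required
#'   in `ligand_aware` mode; ignored in `projected` mode.
#' @param residues Character vector of protein residue identifiers in the
#'   canonical form `"RESNAME+SEQNUM[:CHAIN]"`, e.g. `"ARG63"`.
#' @param mode `"ligand_aware"` (default) or `"projected"`.
#' @return An object of class `hgpm_feature_key` with fields `feature_type`,
#'   `ligand_part`, `environment`, `mode` and the canonical `serial` string.
#' @examples
#' make_feature_key("HBA", "N1", "ARG63")$serial        # "HBA|N1|ARG63"
#' make_feature_key("HBA", "N1", "ARG63", mode = "projected")$serial
#' @export
make_feature_key <- function(feature_type, ligand_atoms = character(0),
                             residues, mode = c("ligand_aware", "projected")) {
  mode <- match.arg(mode)
  if (length(feature_type) != 1L || !feature_type %in% feature_types()) {
    hgpm_stop("hgpm_vocabulary_error",
              "unknown feature type '%s' (known: %s)",
              paste(feature_type, collapse = ","),
              paste(feature_types(), collapse = ", "))
  }
  if (length(residues) == 0L) {
    hgpm_stop("hgpm_invalid_feature", "a feature requires at least one environment residue")
  }
  check_identifiers(residues, "residue")
  residues <- sort_c(unique(residues))
  if (mode == "ligand_aware") {
    if (length(ligand_atoms) == 0L) {
      hgpm_stop("hgpm_invalid_feature",
                "ligand_aware features require at least one ligand atom")
    }
    check_identifiers(ligand_atoms, "ligand atom")
    ligand_atoms <- sort_c(unique(ligand_atoms))
    serial <- paste(feature_type, paste(ligand_atoms, collapse = ","),
                    paste(residues, collapse = ","), sep = "|")
  } else {
    ligand_atoms <- character(0)
    serial <- paste(feature_type, paste(residues, collapse = ","), sep = "|")
  }
  structure(list(feature_type = feature_type, ligand_part = ligand_atoms,
                 environment = residues, mode = mode, serial = serial),
            class = "hgpm_feature_key")
}

#' Parse a feature serial back into a key
#'
#' Inverse of the serialization performed by [make_feature_key()]:
#' `parse_feature_key(key$serial, key$mode)` reproduces `key`.
#'
#' @param serial Canonical serial string.
#' @param mode Mode the serial was produced in.
#' @return An `hgpm_feature_key`.
#' @export
parse_feature_key <- function(serial, mode = c("ligand_aware", "projected")) {
  mode <- match.arg(mode)
  parts <- strsplit(serial, "|", fixed = TRUE)[[1L]]
  expected <- if (mode == "ligand_aware") 3L else 2L
  if (length(parts) != expected) {
    hgpm_stop("hgpm_invalid_feature", "serial '%s' does not have %d '|'-separated parts",
              serial, expected)
  }
  if (mode == "ligand_aware") {
    make_feature_key(parts[1L], strsplit(parts[2L], ",", fixed = TRUE)[[1L]],
                     strsplit(parts[3L], ",", fixed = TRUE)[[1L]], mode)
  } else {
    make_feature_key(parts[1L], character(0),
                     strsplit(parts[2L], ",", fixed = TRUE)[[1L]], mode)
  }
}

#' Project a ligand-aware key onto the protein
#'
#' Drops the ligand atoms from a key, keeping only interaction type and
#' protein residues. Many ligand-aware keys can map to the same projected key.
#'
#' @param key An `hgpm_feature_key`.
#' @return The projected `hgpm_feature_key`.
#' @export
project_feature_key <- function(key) {
  stopifnot(inherits(key, "hgpm_feature_key"))
  make_feature_key(key$feature_type, character(0), key$environment, "projected")
}

#' @export
print.hgpm_feature_key <- function(x, ...) {
  cat("<feature ", x$serial, " (", x$mode, ")>\n", sep = "")
  invisible(x)
}

#' @export
format.hgpm_feature_key <- function(x, ...) x$serial

features_to_serials <- function(features, mode) {
  if (length(features) == 0L) return(character(0))
  if (is.character(features)) return(sort_c(unique(features)))
  serials <- vapply(features, function(f) {
    if (inherits(f, "hgpm_feature_key")) {
      if (f$mode != mode) {
        hgpm_stop("hgpm_mode_error", "feature '%s' has mode %s, model has mode %s",
                  f$serial, f$mode, mode)
      }
      f$serial
    } else {
      hgpm_stop("hgpm_invalid_feature", "features must be keys or serial strings")
    }
  }, character(1))
  sort_c(unique(serials))
}

#' Create a pharmacophore model
#'
#' One model describes the full interaction pattern of a single frame (or a
#' crystal structure when `is_reference = TRUE`): a set of unique feature
#' keys plus provenance. 3D geometry is not stored; `payload_ref` may carry
#' an opaque handle (e.g. a file path) to an external 3D model.
#'
#' @param system_id,run_id,frame_index Provenance: protein-ligand system,
#'   simulation run and 0-based frame number.
#' @param features List of [make_feature_key()] objects or canonical serial
#'   strings; deduplicated and sorted.
#' @param mode Feature-serial mode shared by all features.
#' @param is_reference `TRUE` for crystal-structure-derived models, which are
#'   exempt from appearance-count filtering.
#' @param payload_ref Optional opaque reference to an external 3D model.
#' @return An object of class `hgpm_model`.
#' @export
pharmacophore_model <- function(system_id, run_id, frame_index, features,
                                mode = c("ligand_aware", "projected"),
                                is_reference = FALSE, payload_ref = NULL) {
  mode <- match.arg(mode)
  if (frame_index < 0) hgpm_stop("hgpm_invalid_model", "frame_index must be >= 0")
  structure(list(system_id = as.character(system_id),
                 run_id = as.character(run_id),
                 frame_index = as.integer(frame_index),
                 features = features_to_serials(features, mode),
                 mode = mode,
                 is_reference = isTRUE(is_reference),
                 payload_ref = payload_ref),
            class = "hgpm_model")
}

#' @export
print.hgpm_model <- function(x, ...) {
  cat(sprintf("<pharmacophore model %s/%s/frame %d: %d feature(s)%s>\n",
              x$system_id, x$run_id, x$frame_index, length(x$features),
              if (x$is_reference) ", reference" else ""))
  invisible(x)
}

model_mode <- function(models) {
  modes <- unique(vapply(models, `[[`, character(1), "mode"))
  if (length(modes) != 1L) {
    hgpm_stop("hgpm_mode_error", "models mix feature modes: %s",
              paste(modes, collapse = ", "))
  }
  modes
}

#' Build the catalog of unique features in an ensemble
#'
#' Collects the union of all feature keys over an ensemble of models into an
#' ordered catalog. The catalog fixes the bit positions of every feature
#' vector: entry i corresponds to bit i. Ordering is the lexicographic order
#' of canonical serials, so the catalog (and every downstream bit pattern)
#' is invariant under permutation of the input models.
#'
#' @param models Non-empty list of [pharmacophore_model()] objects sharing
#'   one mode.
#' @return An object of class `hgpm_catalog` with fields `entries` (sorted
#'   serials) and `mode`.
#' @export
build_catalog <- function(models) {
  if (length(models) == 0L) hgpm_stop("hgpm_parameter_error", "no models supplied")
  mode <- model_mode(models)
  entries <- sort_c(unique(unlist(lapply(models, `[[`, "features"))))
  structure(list(entries = entries, mode = mode), class = "hgpm_catalog")
}

#' @export
print.hgpm_catalog <- function(x, ...) {
  cat(sprintf("<feature catalog: %d unique feature(s), mode %s>\n",
              length(x$entries), x$mode))
  invisible(x)
}

#' Convert models into binary feature vectors
#'
#' Each non-empty model becomes a bit pattern aligned to `catalog` (1 =
#' feature present, 0 = absent). Models with an empty feature set yield no
#' vector; their provenance is recorded in the `"skipped"` attribute of the
#' result so they can still be counted towards fractional thresholds.
#'
#' @param models List of [pharmacophore_model()] objects.
#' @param catalog An [build_catalog()] result covering every feature used.
#' @return A `data.frame` with columns `pattern`, `system_id`, `run_id`,
#'   `frame_index`, `is_reference`; attribute `skipped` holds the provenance
#'   of empty models.
#' @export
vectorize <- function(models, catalog) {
  stopifnot(inherits(catalog, "hgpm_catalog"))
  if (length(models) > 0L && model_mode(models) != catalog$mode) {
    hgpm_stop("hgpm_mode_error", "model mode does not match catalog mode")
  }
  entries <- catalog$entries
  nb <- length(entries)
  rows <- lapply(models, function(m) {
    idx <- match(m$features, entries)
    if (anyNA(idx)) {
      hgpm_stop("hgpm_catalog_error",
                "feature(s) not in catalog: %s",
                paste(m$features[is.na(idx)], collapse = ", "))
    }
    bits <- rep(FALSE, nb)
    bits[idx] <- TRUE
    list(pattern = bits_to_pat(bits), system_id = m$system_id, run_id = m$run_id,
         frame_index = m$frame_index, is_reference = m$is_reference,
         empty = length(m$features) == 0L)
  })
  empty <- vapply(rows, `[[`, logical(1), "empty")
  mk <- function(rs) {
    data.frame(pattern = vapply(rs, `[[`, character(1), "pattern"),
               system_id = vapply(rs, `[[`, character(1), "system_id"),
               run_id = vapply(rs, `[[`, character(1), "run_id"),
               frame_index = vapply(rs, `[[`, integer(1), "frame_index"),
               is_reference = vapply(rs, `[[`, logical(1), "is_reference"),
               stringsAsFactors = FALSE)
  }
  out <- mk(rows[!empty])
  attr(out, "skipped") <- if (any(empty)) mk(rows[empty])[-1L] else mk(list())[-1L]
  out
}

#' Collapse feature vectors into counted unique vectors
#'
#' Deduplicates identical bit patterns and counts, for every unique pattern,
#' the number of (non-reference) frames whose model matches it exactly — the
#' appearance count. Frame provenance is kept, sorted by run then frame, so
#' the first model observed with each pattern stays retrievable.
#'
#' @param vectors Output of [vectorize()].
#' @return A `data.frame` (one row per unique pattern, sorted by pattern)
#'   with columns `pattern`, `appearance_count`, `observed`, `reference` and
#'   list-column `frames` (data frames of `system_id`, `run_id`,
#'   `frame_index`).
#' @export
count_unique <- function(vectors) {
  if (nrow(vectors) == 0L) {
    out <- data.frame(pattern = character(0), appearance_count = integer(0),
                      observed = logical(0), reference = logical(0))
    out$frames <- list()
    return(out)
  }
  stopifnot(length(unique(nchar(vectors$pattern))) == 1L)
  groups <- split(seq_len(nrow(vectors)), vectors$pattern)
  pats <- sort_c(names(groups))
  rows <- lapply(pats, function(p) {
    g <- vectors[groups[[p]], , drop = FALSE]
    md <- g[!g$is_reference, c("system_id", "run_id", "frame_index")]
    ord <- order(md$run_id, md$frame_index, method = "radix")
    md <- md[ord, , drop = FALSE]
    rownames(md) <- NULL
    list(pattern = p, appearance_count = nrow(md),
         observed = nrow(md) > 0L, reference = any(g$is_reference), frames = md)
  })
  out <- data.frame(pattern = vapply(rows, `[[`, character(1), "pattern"),
                    appearance_count = vapply(rows, `[[`, integer(1), "appearance_count"),
                    observed = vapply(rows, `[[`, logical(1), "observed"),
                    reference = vapply(rows, `[[`, logical(1), "reference"),
                    stringsAsFactors = FALSE)
  out$frames <- lapply(rows, `[[`, "frames")
  out
}

#' Filter counted vectors by appearance count
#'
#' Removes noise models: unique vectors that were seen fewer times than a
#' threshold. The threshold is given either directly (`min_count`) or as a
#' fraction of the number of initial frames, in which case it is
#' `floor(fraction * n_frames)` bounded below by 2. Reference
#' (crystal-structure) vectors are exempt and always kept.
#'
#' @param counted Output of [count_unique()].
#' @param min_count Absolute threshold (use either this or `fraction`).
#' @param fraction Fraction in (0, 1) of `n_frames`.
#' @param n_frames Number of initial frames (including frames whose model
#'   was empty); required with `fraction`.
#' @return The surviving rows, with attribute `threshold` giving the
#'   threshold actually applied.
#' @export
filter_by_count <- function(counted, min_count = NULL, fraction = NULL,
                            n_frames = NULL) {
  if (is.null(min_count) == is.null(fraction)) {
    hgpm_stop("hgpm_parameter_error",
              "supply exactly one of min_count or fraction")
  }
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction >= 1) {
      hgpm_stop("hgpm_parameter_error", "fraction must lie in (0, 1)")
    }
    if (is.null(n_frames)) {
      hgpm_stop("hgpm_parameter_error", "n_frames is required with fraction")
    }
    threshold <- max(2L, as.integer(floor(fraction * n_frames)))
  } else {
    if (min_count < 1) hgpm_stop("hgpm_parameter_error", "min_count must be >= 1")
    threshold <- as.integer(min_count)
  }
  keep <- counted$appearance_count >= threshold | counted$reference
  out <- counted[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Partition unique features by the runs they occur in
#'
#' Venn-style partition: given the per-run sets of unique features, counts
#' how many features fall in every intersection region (features seen in
#' exactly that combination of runs), plus the size of the grand union.
#'
#' @param catalogs_by_run Named list (>= 2 entries) of character vectors of
#'   feature serials, or of `hgpm_catalog` objects.
#' @return A list with `regions` (named integer vector over all non-empty
#'   run combinations, names like `"run1&run3"`) and `union` (total number
#'   of distinct features). Region counts sum to `union`.
#' @export
run_overlap <- function(catalogs_by_run) {
  if (length(catalogs_by_run) < 2L) {
    hgpm_stop("hgpm_parameter_error", "run_overlap requires at least 2 runs")
  }
  sets <- lapply(catalogs_by_run, function(x) {
    if (inherits(x, "hgpm_catalog")) x$entries else as.character(x)
  })
  run_ids <- names(sets)
  if (is.null(run_ids)) run_ids <- paste0("run", seq_along(sets))
  all_feats <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_feats %in% s, logical(length(all_feats)))
  if (length(all_feats) == 1L) membership <- matrix(membership, nrow = 1L)
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  regions <- integer(nrow(combos))
  names(regions) <- apply(combos, 1L, function(inc) paste(run_ids[unlist(inc)], collapse = "&"))
  for (i in seq_len(nrow(combos))) {
    inc <- unlist(combos[i, ])
    regions[[i]] <- sum(apply(membership, 1L, function(mem) all(mem == inc)))
  }
  list(regions = regions, union = length(all_feats))
}

#' Feature-type composition of a catalog
#'
#' Counts unique features per interaction type (the data behind the
#' composition pie charts). Types absent from the catalog report 0.
#'
#' @param catalog An `hgpm_catalog` (or character vector of serials).
#' @return Named integer vector over [feature_types()]; sums to the catalog
#'   size.
#' @export
type_composition <- function(catalog) {
  entries <- if (inherits(catalog, "hgpm_catalog")) catalog$entries else as.character(catalog)
  types <- sub("\\|.*$", "", entries)
  counts <- table(factor(types, levels = feature_types()))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
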