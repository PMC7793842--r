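# Model-set file formats.
#
# Canonical interchange is JSON Lines: a header object on the first line,
# then one model object per line — streamable for 10,000-frame ensembles.
# CSV (one row per feature) is provided for spreadsheet users. A
# best-effort, explicitly lossy reader for LigandScout-style pharmacophore
# XML (.pml) extracts feature types and name/target annotations only.
# Frame indexing is 0-based throughout.

#' Write a model set to disk
#'
#' @param models List of [pharmacophore_model()] objects (one mode).
#' @param path Output file path.
#' @param format `"jsonl"` (canonical) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(models, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  mode <- model_mode(models)
  if (format == "jsonl") {
    header <- list(hgpm_model_set = 1L, mode = mode,
                   system_id = models[[1L]]$system_id,
                   run_id = models[[1L]]$run_id,
                   n_frames = length(models))
    lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE),
               vapply(models, function(m) {
                 feats <- lapply(m$features, function(s) {
                   k <- parse_feature_key(s, m$mode)
                   list(type = k$feature_type,
                        ligand_atoms = I(k$ligand_part),
                        residues = I(k$environment))
                 })
                 rec <- list(system_id = m$system_id, run_id = m$run_id,
                             frame_index = m$frame_index,
                             is_reference = m$is_reference,
                             features = feats)
                 if (!is.null(m$payload_ref)) rec$payload_ref <- m$payload_ref
                 extra <- attr(m, "extra")
                 if (!is.null(extra)) rec[names(extra)] <- extra
                 as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
               }, character(1)))
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, lapply(models, function(m) {
      if (length(m$features) == 0L) {
        return(data.frame(system_id = m$system_id, run_id = m$run_id,
                          frame_index = m$frame_index, mode = m$mode,
                          is_reference = m$is_reference,
                          feature_type = "", ligand_atoms = "", residues = "",
                          stringsAsFactors = FALSE))
      }
      do.call(rbind, lapply(m$features, function(s) {
        k <- parse_feature_key(s, m$mode)
        data.frame(system_id = m$system_id, run_id = m$run_id,
                   frame_index = m$frame_index, mode = m$mode,
                   is_reference = m$is_reference,
                   feature_type = k$feature_type,
                   ligand_atoms = paste(k$ligand_part, collapse = ";"),
                   residues = paste(k$environment, collapse = ";"),
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a model set from disk
#'
#' @param path Input file.
#' @param format `"jsonl"`, `"csv"` or `"pml"` (LigandScout-style XML,
#'   best-effort and lossy).
#' @return List of [pharmacophore_model()] objects; jsonl headers are
#'   attached as attribute `header`.
#' @export
read_model_set <- function(path, format = c("jsonl", "csv", "pml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    hgpm_stop("hgpm_io_error", "file not found: %s", path)
  }
  switch(format,
         jsonl = read_model_set_jsonl(path),
         csv = read_model_set_csv(path),
         pml = read_model_set_pml(path))
}

record_to_model <- function(rec, mode, where) {
  feats <- lapply(rec$features, function(f) {
    if (is.null(f$type)) {
      hgpm_stop("hgpm_parse_error", "%s: feature without a type", where)
    }
    tryCatch(
      make_feature_key(f$type, unlist(f$ligand_atoms), unlist(f$residues), mode),
      hgpm_vocabulary_error = function(e) {
        hgpm_stop("hgpm_vocabulary_error", "%s: %s", where, conditionMessage(e))
      })
  })
  m <- pharmacophore_model(rec$system_id, rec$run_id, rec$frame_index, feats,
                           mode = mode,
                           is_reference = isTRUE(rec$is_reference),
                           payload_ref = rec$payload_ref)
  known <- c("system_id", "run_id", "frame_index", "is_reference", "features",
             "payload_ref")
  extra <- rec[setdiff(names(rec), known)]
  if (length(extra) > 0L) attr(m, "extra") <- extra
  m
}

read_model_set_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) hgpm_stop("hgpm_parse_error", "%s: empty file", path)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
             error = function(e) {
               hgpm_stop("hgpm_parse_error", "%s line %d: malformed JSON (%s)",
                         path, i, conditionMessage(e))
             })
  }
  header <- parse_line(1L)
  if (is.null(header$hgpm_model_set)) {
    hgpm_stop("hgpm_parse_error", "%s line 1: missing model-set header", path)
  }
  mode <- header$mode %||% "ligand_aware"
  models <- lapply(seq_along(lines)[-1L], function(i) {
    record_to_model(parse_line(i), mode, sprintf("%s line %d", path, i))
  })
  attr(models, "header") <- header
  models
}

read_model_set_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("system_id", "run_id", "frame_index", "mode", "is_reference",
              "feature_type", "ligand_atoms", "residues")
  if (!all(needed %in% names(df))) {
    hgpm_stop("hgpm_parse_error", "%s: missing column(s) %s", path,
              paste(setdiff(needed, names(df)), collapse = ", "))
  }
  for (col in c("feature_type", "ligand_atoms", "residues")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  key <- paste(df$system_id, df$run_id, df$frame_index, sep = "\r")
  models <- lapply(unique(key), function(k) {
    g <- df[key == k, , drop = FALSE]
    feats <- lapply(which(nzchar(g$feature_type)), function(i) {
      tryCatch(
        make_feature_key(g$feature_type[i],
                         strsplit(g$ligand_atoms[i], ";", fixed = TRUE)[[1L]],
                         strsplit(g$residues[i], ";", fixed = TRUE)[[1L]],
                         g$mode[i]),
        hgpm_vocabulary_error = function(e) {
          hgpm_stop("hgpm_vocabulary_error", "%s row %d: %s", path,
                    which(key == k)[i], conditionMessage(e))
        })
    })
    pharmacophore_model(g$system_id[1L], g$run_id[1L], g$frame_index[1L],
                        feats, mode = g$mode[1L],
                        is_reference = isTRUE(as.logical(g$is_reference[1L])))
  })
  models
}

pml_type_map <- c(H = "H", HBA = "HBA", HBD = "HBD", AR = "AR", PI = "PI",
                  NI = "NI", XBD = "XBD")

read_model_set_pml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    hgpm_stop("hgpm_parse_error", "%s: not parseable XML (%s)",
                              path, conditionMessage(e))
                  })
  phs <- xml2::xml_find_all(doc, "//pharmacophore")
  if (length(phs) == 0L) phs <- list(doc)
  models <- lapply(seq_along(phs), function(i) {
    ph <- phs[[i]]
    els <- xml2::xml_find_all(ph, ".//point | .//plane | .//vector | .//volume")
    feats <- list()
    skipped <- 0L
    for (el in els) {
      nm <- xml2::xml_attr(el, "name")
      type <- pml_type_map[nm]
      atoms <- xml2::xml_attr(el, "ligandAtoms")
      res <- xml2::xml_attr(el, "targetResidues")
      if (is.na(type) || is.na(res)) { skipped <- skipped + 1L; next }
      atoms <- if (is.na(atoms)) "LIG" else atoms
      feats[[length(feats) + 1L]] <-
        make_feature_key(unname(type), strsplit(atoms, ";")[[1L]],
                         strsplit(res, ";")[[1L]], "ligand_aware")
    }
    if (skipped > 0L) {
      message(sprintf("%s: pharmacophore %d: skipped %d feature(s) without type/residue annotation",
                      path, i, skipped))
    }
    nm <- xml2::xml_attr(ph, "name")
    pharmacophore_model(system_id = if (is.na(nm)) basename(path) else nm,
                        run_id = "pml", frame_index = i - 1L, feats,
                        mode = "ligand_aware", payload_ref = path)
  })
  models
}
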