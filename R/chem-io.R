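# Reading, canonicalizing, deduplicating and merging labeled molecule
# collections. A molecule set is a plain data.frame (class "npek_molecule_set")
# with columns mol_id, smiles (canonical), source ("background"/"epitope"),
# label_b, label_t, so the usual data.frame verbs keep working.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Canonicalization is a fixed
#' point: feeding the output back in returns the identical string, and two
#' spellings of the same structure (e.g. `"OCC"` and `"CCO"`) map to the same
#' canonical form.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` for unparsable entries.
#' @examples
#' canonical_smiles(c("OCC", "CCO", "C1CC1"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  todo <- which(!is.na(smiles) & nzchar(smiles))
  # OpenBabel stops at the first invalid record of a batch, so conversion is
  # restarted after each failure; titles keep input/output rows aligned.
  while (length(todo) > 0L) {
    input <- paste0(smiles[todo], " t", seq_along(todo), collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", input),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    done <- 0L
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) next
      idx <- suppressWarnings(as.integer(sub("^t", "", trimws(parts[2]))))
      if (is.na(idx)) next
      out[todo[idx]] <- trimws(parts[1])
      done <- max(done, idx)
    }
    if (done >= length(todo)) break
    # record done+1 failed; resume after it
    todo <- todo[-seq_len(done + 1L)]
  }
  out
}

#' Parse one SMILES string into a molecule record
#'
#' @param smiles_text A single SMILES string.
#' @param mol_id Identifier; defaults to the canonical SMILES itself.
#' @param source `"background"` or `"epitope"`.
#' @param label_b,label_t Logical assay labels. Background molecules must be
#'   unlabeled; a true label forces `source = "epitope"`.
#' @return A one-row molecule set (see [molecule_set()]).
#' @examples
#' parse_smiles("OCC")$smiles  # "CCO"
#' @export
parse_smiles <- function(smiles_text, mol_id = NULL, source = "background",
                         label_b = FALSE, label_t = FALSE) {
  if (!is.character(smiles_text) || length(smiles_text) != 1L || !nzchar(smiles_text))
    npek_stop("smiles_text must be a single non-empty string", "npek_parse_error")
  can <- canonical_smiles(smiles_text)
  if (is.na(can) || !nzchar(can))
    npek_stop(paste0("unparsable SMILES: '", smiles_text, "'"), "npek_parse_error",
              smiles = smiles_text)
  molecule_set(
    mol_id = mol_id %||% can, smiles = can, source = source,
    label_b = label_b, label_t = label_t, canonicalize = FALSE
  )
}

#' Construct a molecule set
#'
#' @param mol_id Character identifiers (unique).
#' @param smiles SMILES strings (canonicalized unless `canonicalize = FALSE`).
#' @param source `"background"` or `"epitope"`, recycled.
#' @param label_b,label_t Logical assay labels, recycled.
#' @param provenance Free-text metadata attached as an attribute.
#' @param canonicalize Set to `FALSE` when `smiles` are already canonical.
#' @return A data.frame of class `"npek_molecule_set"`.
#' @export
molecule_set <- function(mol_id, smiles, source = "background",
                         label_b = FALSE, label_t = FALSE,
                         provenance = NULL, canonicalize = TRUE) {
  n <- length(smiles)
  if (canonicalize && n > 0L) {
    can <- canonical_smiles(smiles)
    if (anyNA(can))
      npek_stop(paste0("unparsable SMILES: '",
                       paste(smiles[is.na(can)], collapse = "', '"), "'"),
                "npek_parse_error")
    smiles <- can
  }
  label_b <- rep_len(as.logical(label_b), n)
  label_t <- rep_len(as.logical(label_t), n)
  source <- rep_len(as.character(source), n)
  if (!all(source %in% c("background", "epitope")))
    npek_stop("source must be 'background' or 'epitope'", "npek_config_error")
  # a background molecule with a positive assay label is promoted to epitope
  source[label_b | label_t] <- "epitope"
  ms <- data.frame(
    mol_id = as.character(rep_len(mol_id, n)), smiles = smiles,
    source = source, label_b = label_b, label_t = label_t,
    stringsAsFactors = FALSE
  )
  attr(ms, "provenance") <- provenance
  class(ms) <- c("npek_molecule_set", "data.frame")
  ms
}

#' @export
`[.npek_molecule_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- class(x)
    attr(out, "provenance") <- attr(x, "provenance")
  }
  out
}

#' @export
print.npek_molecule_set <- function(x, ...) {
  cat("<npek molecule set> ", nrow(x), " molecules (",
      sum(x$source == "epitope"), " epitopes; B+: ", sum(x$label_b),
      ", T+: ", sum(x$label_t), ")\n", sep = "")
  if (!is.null(attr(x, "provenance")))
    cat("provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

.parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  v[is.na(v)] <- ""   # absent labels count as negative
  out <- v %in% c("1", "true", "t", "yes")
  bad <- !v %in% c("0", "1", "true", "false", "t", "f", "yes", "no", "", "na")
  if (any(bad))
    npek_stop(paste0("cannot interpret label value(s): ",
                     paste(unique(v[bad]), collapse = ", ")), "npek_config_error")
  out
}

#' Load a labeled molecule collection from a file
#'
#' Reads CSV (header required; configurable SMILES column), SMILES (`.smi`,
#' one record per line, optional identifier after whitespace) or SDF (labels
#' from named data fields). Records whose structure fails to parse are
#' dropped and counted in the attached load report
#' (`attr(x, "load_report")`).
#'
#' @param path File path.
#' @param format `"csv"`, `"smi"` or `"sdf"`; guessed from the extension by
#'   default.
#' @param smiles_col,id_col,label_b_col,label_t_col Column / SDF-field names.
#' @param source Source tag applied to every record.
#' @return A molecule set with a `load_report` attribute
#'   (`list(accepted, rejected, rejected_records)`).
#' @export
load_dataset <- function(path, format = c("auto", "csv", "smi", "sdf"),
                         smiles_col = "smiles", id_col = "id",
                         label_b_col = "label_b", label_t_col = "label_t",
                         source = "background") {
  format <- match.arg(format)
  if (!file.exists(path))
    npek_stop(paste0("file not found: ", path), "npek_config_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", smi = "smi", sdf = "sdf",
                     npek_stop(paste0("cannot guess format of ", path),
                               "npek_config_error"))
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!smiles_col %in% names(df))
      npek_stop(paste0("CSV lacks the SMILES column '", smiles_col, "'"),
                "npek_config_error")
    raw <- as.character(df[[smiles_col]])
    ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else raw
    lb <- if (label_b_col %in% names(df)) .parse_bool(df[[label_b_col]]) else FALSE
    lt <- if (label_t_col %in% names(df)) .parse_bool(df[[label_t_col]]) else FALSE
  } else if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    raw <- vapply(toks, `[[`, "", 1L)
    ids <- vapply(toks, function(t) if (length(t) > 1L) t[2] else t[1], "")
    lb <- FALSE; lt <- FALSE
  } else { # sdf
    sdf <- ChemmineR::read.SDFset(path)
    smi <- ChemmineR::sdf2smiles(sdf)
    raw <- unname(as.character(smi))
    props <- ChemmineR::datablock(sdf)
    getprop <- function(rec, key) if (key %in% names(rec)) rec[[key]] else NA
    ids <- vapply(seq_along(props), function(i) {
      v <- getprop(props[[i]], id_col)
      if (is.na(v)) paste0("sdf_", i) else as.character(v)
    }, "")
    lb <- .parse_bool(vapply(props, function(p) as.character(getprop(p, label_b_col)), ""))
    lt <- .parse_bool(vapply(props, function(p) as.character(getprop(p, label_t_col)), ""))
  }

  n <- length(raw)
  lb <- rep_len(lb, n); lt <- rep_len(lt, n)
  can <- if (n > 0L) canonical_smiles(raw) else character()
  ok <- !is.na(can) & nzchar(can)
  if (n > 0L && !any(ok))
    npek_stop(paste0("no parsable structures in ", path), "npek_empty_set_error")
  ms <- molecule_set(
    mol_id = ids[ok], smiles = can[ok], source = source,
    label_b = lb[ok], label_t = lt[ok],
    provenance = paste0(path, " (read ", format(Sys.Date()), ")"),
    canonicalize = FALSE
  )
  attr(ms, "load_report") <- list(
    accepted = sum(ok), rejected = sum(!ok),
    rejected_records = raw[!ok]
  )
  ms
}

#' Remove duplicate structures from a molecule set
#'
#' Molecules sharing a canonical SMILES are collapsed to one record: the
#' first occurrence keeps its `mol_id` and position, assay labels of all
#' copies are OR-merged (a molecule positive in any record is positive), and
#' the survivor is tagged `epitope` if any copy was. Idempotent.
#'
#' @param ms A molecule set.
#' @return A molecule set with unique canonical SMILES.
#' @export
deduplicate <- function(ms) {
  stopifnot(inherits(ms, "npek_molecule_set"))
  if (nrow(ms) == 0L) return(ms)
  grp <- match(ms$smiles, unique(ms$smiles))
  keep <- !duplicated(grp)
  out <- ms[keep, , drop = FALSE]
  out$label_b <- as.logical(tapply(ms$label_b, grp, any))[grp[keep]]
  out$label_t <- as.logical(tapply(ms$label_t, grp, any))[grp[keep]]
  out$source[out$label_b | out$label_t |
               tapply(ms$source == "epitope", grp, any)[grp[keep]]] <- "epitope"
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(ms, "provenance")
  class(out) <- class(ms)
  out
}

#' Merge a background set with positive (epitope) sets
#'
#' Union of both sets. A canonical SMILES present in both keeps the positive
#' record (labels and `source = "epitope"`); the background copy is dropped.
#'
#' @param background,positives Deduplicated molecule sets.
#' @return The merged, deduplicated molecule set (background rows first).
#' @export
merge_background_positives <- function(background, positives) {
  stopifnot(inherits(background, "npek_molecule_set"),
            inherits(positives, "npek_molecule_set"))
  if (anyDuplicated(background$smiles) || anyDuplicated(positives$smiles))
    npek_stop("inputs must be individually deduplicated (see deduplicate())",
              "npek_config_error")
  shared <- background$smiles %in% positives$smiles
  out <- rbind(background[!shared, , drop = FALSE], positives)
  rownames(out) <- NULL
  attr(out, "provenance") <- paste(
    "merged:", attr(background, "provenance") %||% "background", "+",
    attr(positives, "provenance") %||% "positives"
  )
  class(out) <- class(background)
  out
}

#' Write a molecule set to a canonical CSV file
#'
#' @param ms A molecule set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_csv <- function(ms, path) {
  stopifnot(inherits(ms, "npek_molecule_set"))
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}
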