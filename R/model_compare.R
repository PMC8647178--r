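#' Protein model as an ordered residue table
#'
#' A `structure_model` is a data frame with one row per polymer residue:
#' `chain_id`, `seq_num`, `insertion_code` (empty string when none),
#' `residue_type` (3-letter code, compared verbatim), and the C-alpha
#' coordinates `x`, `y`, `z` in Angstrom (all `NA` when the residue has no
#' C-alpha atom).
#'
#' @param residues Data frame with the columns above.
#' @return The validated data frame with class `structure_model`.
#' @export
structure_model <- function(residues) {
  req <- c("chain_id", "seq_num", "insertion_code", "residue_type", "x", "y", "z")
  missing <- setdiff(req, names(residues))
  if (length(missing))
    stop("residue table lacks columns: ", paste(missing, collapse = ", "))
  if (any(!nzchar(residues$residue_type)))
    stop("residue_type must be a non-empty code")
  key <- paste(residues$chain_id, residues$seq_num, residues$insertion_code)
  if (anyDuplicated(key))
    stop("duplicate (chain_id, seq_num, insertion_code) residue keys")
  residues <- as.data.frame(residues)[, req]
  class(residues) <- c("structure_model", "data.frame")
  residues
}

#' Read a protein model from PDB or mmCIF
#'
#' Keeps one entry per polymer (ATOM-record) residue. When a residue's
#' C-alpha is present in several alternate locations, the highest-occupancy
#' altloc wins (ties broken by file order). Residues with no C-alpha atom are
#' kept with `NA` coordinates.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` coordinate file.
#' @return A [structure_model].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  # read.cif emits beta-status notices; parse problems still surface as errors
  obj <- if (is_cif) suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE))
         else bio3d::read.pdb(path, rm.alt = FALSE)
  atoms <- obj$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop(errorCondition("model contains no polymer residues",
                        class = c("mbperf_empty_model", "error")))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first_idx <- which(!duplicated(key))
  res <- data.frame(
    chain_id = atoms$chain[first_idx],
    seq_num = atoms$resno[first_idx],
    insertion_code = atoms$insert[first_idx],
    residue_type = atoms$resid[first_idx],
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca)) {
    ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
    # highest occupancy wins; stable order keeps the first on ties
    ord <- order(ca_key, -ca$o)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(ca_key[ord]), , drop = FALSE]
    m <- match(paste(res$chain_id, res$seq_num, res$insertion_code, sep = "\r"),
               paste(ca$chain, ca$resno, ca$insert, sep = "\r"))
    hit <- !is.na(m)
    res$x[hit] <- ca$x[m[hit]]
    res$y[hit] <- ca$y[m[hit]]
    res$z[hit] <- ca$z[m[hit]]
  }
  structure_model(res)
}

#' Write a structure model as PDB or mmCIF
#'
#' Emits one C-alpha ATOM record per residue with coordinates; residues
#' lacking a C-alpha are skipped on output (they carry no atoms).
#'
#' @param model A [structure_model].
#' @param path Output path; format chosen by extension (`.cif`/`.mmcif` for
#'   mmCIF, PDB otherwise).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  m <- model[!is.na(model$x), , drop = FALSE]
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    lines <- c("data_model", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num")
    rows <- sprintf(
      "ATOM %d C CA . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s CA 1",
      seq_len(nrow(m)), m$residue_type, m$chain_id, m$seq_num,
      ifelse(nzchar(m$insertion_code), m$insertion_code, "?"),
      m$x, m$y, m$z, m$seq_num, m$residue_type, m$chain_id)
    writeLines(c(lines, rows, "#"), path)
  } else {
    rows <- paste0(
      "ATOM  ", sprintf("%5d", seq_len(nrow(m))), "  CA  ",
      sprintf("%-3s", m$residue_type), " ", m$chain_id,
      sprintf("%4d", m$seq_num),
      ifelse(nzchar(m$insertion_code), substr(m$insertion_code, 1, 1), " "),
      "   ", sprintf("%8.3f%8.3f%8.3f", m$x, m$y, m$z),
      "  1.00  0.00           C")
    writeLines(c(rows, "END"), path)
  }
  invisible(path)
}

#' Structure completeness between a built and a deposited model
#'
#' The completeness of a built model is the fraction of residues in the
#' deposited (reference) model that are reproduced in the built model. A
#' deposited residue counts as reproduced when some built residue has the
#' same residue type and a C-alpha to C-alpha distance strictly below the
#' cutoff (default 1 Angstrom). Matching is one-to-one, assigned greedily by
#' ascending distance. Deposited residues without a C-alpha are excluded from
#' the denominator.
#'
#' @param built,deposited [structure_model] objects. Both are assumed to be in
#'   the same crystal frame; no superposition is performed.
#' @param cutoff Distance cutoff in Angstrom (strict inequality).
#' @return An object of class `completeness_result`: a list with
#'   `completeness` (fraction in \[0, 1\]), `n_deposited`, `n_matched` and
#'   `matched_pairs` (data frame of built/deposited row indices and distance).
#' @export
structure_completeness <- function(built, deposited, cutoff = 1.0) {
  stopifnot(inherits(built, "structure_model"),
            inherits(deposited, "structure_model"))
  dep <- which(!is.na(deposited$x))
  if (length(dep) == 0L)
    stop("deposited model has no C-alpha atoms; completeness undefined")
  blt <- which(!is.na(built$x))

  pairs <- data.frame(built = integer(), deposited = integer(),
                      distance = numeric())
  if (length(blt)) {
    # candidate pairs restricted to equal residue type, then thresholded
    for (ty in unique(deposited$residue_type[dep])) {
      di <- dep[deposited$residue_type[dep] == ty]
      bi <- blt[built$residue_type[blt] == ty]
      if (!length(bi)) next
      dx <- outer(built$x[bi], deposited$x[di], "-")
      dy <- outer(built$y[bi], deposited$y[di], "-")
      dz <- outer(built$z[bi], deposited$z[di], "-")
      dist <- sqrt(dx^2 + dy^2 + dz^2)
      ok <- which(dist < cutoff, arr.ind = TRUE)
      if (nrow(ok))
        pairs <- rbind(pairs, data.frame(built = bi[ok[, 1]],
                                         deposited = di[ok[, 2]],
                                         distance = dist[ok]))
    }
  }
  matched <- pairs[0, ]
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$distance, pairs$built, pairs$deposited), ]
    used_b <- logical(nrow(built)); used_d <- logical(nrow(deposited))
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      b <- pairs$built[i]; d <- pairs$deposited[i]
      if (!used_b[b] && !used_d[d]) {
        keep[i] <- TRUE; used_b[b] <- TRUE; used_d[d] <- TRUE
      }
    }
    matched <- pairs[keep, , drop = FALSE]
    rownames(matched) <- NULL
  }
  structure(list(completeness = nrow(matched) / length(dep),
                 n_deposited = length(dep),
                 n_matched = nrow(matched),
                 matched_pairs = matched,
                 cutoff = cutoff),
            class = "completeness_result")
}

#' @export
print.completeness_result <- function(x, ...) {
  cat(sprintf("structure completeness: %.3f (%d of %d deposited residues, cutoff %g A)\n",
              x$completeness, x$n_matched, x$n_deposited, x$cutoff))
  invisible(x)
}
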