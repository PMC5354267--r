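#' Write a protein sequence to FASTA
#' @param sequence single residue string.
#' @param file output path.
#' @param name FASTA header name.
#' @export
write_sequence_fasta <- function(sequence, file, name = "synthetic") {
  seqinr::write.fasta(paste(as_residue_vector(sequence), collapse = ""),
                      names = name, file.out = file, as.string = TRUE)
  invisible(file)
}

#' Read the first sequence from a FASTA file
#' @param file FASTA path.
#' @return single uppercase residue string.
#' @export
read_sequence_fasta <- function(file) {
  s <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE)
  toupper(as.character(s[[1]]))
}

#' Write a Calpha (optionally backbone) structure as PDB ATOM records
#'
#' Emits standard fixed-width ATOM records, chain A, one residue per
#' sequence position; unresolved residues are simply absent, as in a real
#' crystal structure with disordered regions.
#'
#' @param struct an \code{xl_structure}.
#' @param file output path.
#' @export
write_structure_pdb <- function(struct, file) {
  stopifnot(inherits(struct, "xl_structure"))
  res <- struct$residues
  lines <- character(0)
  serial <- 0L
  emit <- function(atom, aa, pos, x, y, z) {
    serial <<- serial + 1L
    el <- substr(atom, 1, 1)
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, paste0(" ", atom), bio3d::aa123(aa), pos, x, y, z, el)
  }
  if (!is.null(struct$atoms)) {
    at <- struct$atoms
    for (k in seq_len(nrow(at))) {
      lines <- c(lines, emit(at$atom[k], at$aa[k], at$pos[k],
                             at$x[k], at$y[k], at$z[k]))
    }
  } else {
    keep <- which(res$resolved)
    for (k in keep) {
      lines <- c(lines, emit("CA", res$aa[k], res$pos[k],
                             res$x[k], res$y[k], res$z[k]))
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Write a PSM table (tab-delimited, canonical column layout)
#' @param psms PSM data.frame.
#' @param file output path.
#' @export
write_psm_table <- function(psms, file) {
  utils::write.table(psms, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a PSM table
#'
#' Reads the canonical tab-delimited layout produced by
#' \code{\link{write_psm_table}}. Third-party exports with different
#' column names can be mapped with \code{col_map}, a named character
#' vector \code{c(canonical = "exported_name", ...)}.
#'
#' @param file path to a delimited PSM table.
#' @param col_map optional canonical-to-exported column name mapping.
#' @param sep field separator.
#' @return PSM data.frame with canonical columns.
#' @export
read_psm_table <- function(file, col_map = NULL, sep = "\t") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(d)) {
        stop("mapped column not found: ", col_map[[canon]])
      }
      names(d)[names(d) == col_map[[canon]]] <- canon
    }
  }
  needed <- c("psm_id", "run_id", "pep_seq_a", "pep_seq_b", "link_pos_a",
              "link_pos_b", "prot_pos_a", "prot_pos_b", "score",
              "is_decoy_a", "is_decoy_b")
  miss <- setdiff(needed, names(d))
  if (length(miss)) stop("PSM table missing columns: ",
                         paste(miss, collapse = ", "))
  d$is_decoy_a <- as.logical(d$is_decoy_a)
  d$is_decoy_b <- as.logical(d$is_decoy_b)
  if (any(d$score < 0)) stop("negative PSM scores")
  d
}

#' Write / read a two-column secondary-structure annotation
#'
#' Format: header \code{position<TAB>label}; DSSP eight-state codes are
#' collapsed on read (E,B -> E; H,G,I -> H; everything else -> C).
#'
#' @param ss character vector of per-residue labels.
#' @param file path.
#' @export
write_ss_annotation <- function(ss, file) {
  utils::write.table(data.frame(position = seq_along(ss), label = ss),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ss_annotation
#' @return \code{read_ss_annotation}: character vector of collapsed
#'   H/E/C labels indexed by position.
#' @export
read_ss_annotation <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lab <- toupper(as.character(d$label))
  out <- ifelse(lab %in% c("E", "B"), "E",
                ifelse(lab %in% c("H", "G", "I"), "H", "C"))
  out[order(d$position)]
}

#' Write ground truth as JSON
#' @param truth list with \code{true_links} and \code{psm_labels}.
#' @param file path.
#' @export
write_ground_truth <- function(truth, file) {
  jsonlite::write_json(list(
    true_links = apply(truth$true_links, 1, function(r)
      list(i = r[[1]], j = r[[2]])),
    psm_labels = as.list(truth$psm_labels)
  ), file, auto_unbox = TRUE)
  invisible(file)
}

#' Write accepted residue pairs as CSV
#'
#' Columns: pos_a, pos_b, score, q_value, n_psms, runs
#' (semicolon-separated run ids of the supporting PSMs).
#'
#' @param pairs residue-pair data.frame from
#'   \code{\link{hierarchical_fdr}} results.
#' @param file path.
#' @export
write_residue_pairs_csv <- function(pairs, file) {
  utils::write.csv(pairs, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a full synthetic bundle to disk
#'
#' FASTA, PDB, PSM table, SS annotation and ground-truth JSON, the
#' external interface of the generator.
#'
#' @param dataset result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths.
#' @export
write_synthetic_bundle <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    pdb = file.path(dir, paste0(prefix, ".pdb")),
    psms = file.path(dir, paste0(prefix, "_psms.tsv")),
    ss = file.path(dir, paste0(prefix, "_ss.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_sequence_fasta(dataset$sequence, paths["fasta"], prefix)
  write_structure_pdb(dataset$structure, paths["pdb"])
  write_psm_table(dataset$psms, paths["psms"])
  write_ss_annotation(dataset$ss, paths["ss"])
  write_ground_truth(dataset$truth, paths["truth"])
  paths
}
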