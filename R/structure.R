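#' Numeric score of a classification call
#'
#' Signed score used for structure colouring: -1 accelerated, +1
#' decelerated, 0 unchanged; scaled by onset strength (1.0 when detected at
#' both 6 and 12 min, 0.5 when only at 12 min).
#'
#' @param label Classification label(s).
#' @param onset Onset tier(s).
#' @return Numeric score(s) in `{-1, -0.5, 0, 0.5, 1}`.
#' @export
classification_score <- function(label, onset) {
  sign <- dplyr::case_when(
    label == "accelerated" ~ -1,
    label == "decelerated" ~ 1,
    .default = 0
  )
  weight <- dplyr::case_when(
    onset == "at_6_and_12" ~ 1,
    onset == "only_12" ~ 0.5,
    .default = 0
  )
  sign * weight
}

#' Map classification calls onto a PDB structure
#'
#' Writes a copy of the coordinate file with each classified residue's
#' numeric score in the temperature-factor column of its atoms (renderable
#' by any structure viewer), plus a plain-text per-residue attribute file
#' `chain resnum label score`. Unclassified residues get a temperature
#' factor of 0; classified residues absent from the chain are skipped with a
#' warning.
#'
#' @param classification A `thz_classification` tibble (one condition).
#' @param pdb_file Path to a PDB coordinate file; the first model is used.
#' @param chain Chain identifier (default `"A"`).
#' @param out_pdb,out_attr Output paths for the annotated PDB and the
#'   attribute TSV.
#' @return Invisibly, a tibble of the written annotations
#'   (`chain`, `residue_number`, `label`, `onset`, `score`).
#' @export
annotate_structure <- function(classification, pdb_file, chain = "A",
                               out_pdb, out_attr) {
  if (!nrow(classification)) stop("empty classification set", call. = FALSE)
  if (length(unique(classification$condition %||% "x")) > 1) {
    stop("annotate one condition at a time", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(pdb_file, multi = FALSE, verbose = FALSE)
  ann <- classification |>
    dplyr::transmute(
      chain = chain,
      residue_number = .data$residue_number,
      label = .data$label,
      onset = .data$onset,
      score = classification_score(.data$label, .data$onset)
    )
  in_chain <- pdb$atom$chain == chain
  if (!any(in_chain)) {
    stop("chain '", chain, "' not found in ", pdb_file, call. = FALSE)
  }
  present <- ann$residue_number %in% unique(pdb$atom$resno[in_chain])
  if (any(!present)) {
    warning("residue(s) ",
            paste(ann$residue_number[!present], collapse = ", "),
            " not in chain ", chain, "; skipped", call. = FALSE)
  }
  ann_used <- ann[present, ]
  b <- rep(0, nrow(pdb$atom))
  hit <- in_chain & pdb$atom$resno %in% ann_used$residue_number
  b[hit] <- ann_used$score[match(pdb$atom$resno[hit],
                                 ann_used$residue_number)]
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_pdb)
  readr::write_tsv(ann_used, out_attr)
  invisible(ann_used)
}

#' Read back the per-residue attribute file
#' @param path Attribute TSV written by [annotate_structure()].
#' @export
read_structure_attributes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Count classification calls
#'
#' @param classification A `thz_classification` tibble.
#' @param residues Optional residue table; when given, counts are also
#'   broken down by hydropathy class.
#' @return Tibble of counts per (`label`, `onset`) (and `hydropathy_class`
#'   when available); counts sum to the number of classified residues.
#' @export
summary_table <- function(classification, residues = NULL) {
  x <- classification
  if (!is.null(residues)) {
    x <- dplyr::left_join(
      x, dplyr::select(residues, "residue_number", "hydropathy_class"),
      by = "residue_number"
    )
    return(dplyr::count(x, .data$hydropathy_class, .data$label, .data$onset,
                        name = "n"))
  }
  dplyr::count(x, .data$label, .data$onset, name = "n")
}

#' Write a synthetic CA-only ubiquitin coordinate file
#'
#' A stand-in coordinate file for examples and tests: the true 76-residue
#' ubiquitin sequence and numbering on chain A, but with synthetic CA
#' coordinates laid out along a smooth helical curve. It is NOT the
#' crystallographic structure — only residue numbering and chain topology
#' are meaningful, which is all the annotation step needs.
#'
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_synthetic_ubiquitin_pdb <- function(path) {
  seq1 <- strsplit(paste0(
    "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQ",
    "QRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"
  ), "")[[1]]
  stopifnot(length(seq1) == 76)
  aa3 <- bio3d::aa123(seq1)
  n <- length(seq1)
  i <- seq_len(n)
  xyz <- as.numeric(rbind(
    10 * cos(i / 3) + 0.5 * i,
    10 * sin(i / 3),
    1.5 * i
  ))
  bio3d::write.pdb(
    file = path,
    xyz = round(xyz, 3),
    resno = i,
    resid = aa3,
    chain = rep("A", n),
    elety = rep("CA", n),
    o = rep(1, n),
    b = rep(0, n)
  )
  invisible(path)
}
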