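#' @noRd
#' Canonical 37-gene vocabulary
CANONICAL_PCGS <- c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
                    "cox1", "cox2", "cox3", "cob", "atp6", "atp8")
CANONICAL_TRNAS <- c("F", "V", "L1", "I", "Q", "M", "W", "A", "N", "C", "Y",
                     "S1", "D", "K", "G", "R", "H", "S2", "L2", "E", "T", "P")
CANONICAL_RRNAS <- c("rrnS", "rrnL")

# three-letter -> one-letter amino-acid codes for tRNA names
AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# explicit synonym table for non-tRNA names (keys are squashed-uppercase)
GENE_SYNONYMS <- local({
  syn <- list(
    nad1 = c("ND1", "NAD1", "NADH1", "NADH DEHYDROGENASE SUBUNIT 1", "NADHDEHYDROGENASESUBUNIT1", "MT-ND1"),
    nad2 = c("ND2", "NAD2", "NADH2", "NADHDEHYDROGENASESUBUNIT2", "MT-ND2"),
    nad3 = c("ND3", "NAD3", "NADH3", "NADHDEHYDROGENASESUBUNIT3", "MT-ND3"),
    nad4 = c("ND4", "NAD4", "NADH4", "NADHDEHYDROGENASESUBUNIT4", "MT-ND4"),
    nad4l = c("ND4L", "NAD4L", "NADH4L", "NADHDEHYDROGENASESUBUNIT4L", "MT-ND4L"),
    nad5 = c("ND5", "NAD5", "NADH5", "NADHDEHYDROGENASESUBUNIT5", "MT-ND5"),
    nad6 = c("ND6", "NAD6", "NADH6", "NADHDEHYDROGENASESUBUNIT6", "MT-ND6"),
    cox1 = c("COX1", "COXI", "COI", "CO1", "COX-1", "MT-CO1",
             "CYTOCHROMECOXIDASESUBUNIT1", "CYTOCHROMECOXIDASESUBUNITI",
             "CYTOCHROMEOXIDASESUBUNIT1", "CYTOCHROMEOXIDASESUBUNITI"),
    cox2 = c("COX2", "COXII", "COII", "CO2", "MT-CO2",
             "CYTOCHROMECOXIDASESUBUNIT2", "CYTOCHROMECOXIDASESUBUNITII"),
    cox3 = c("COX3", "COXIII", "COIII", "CO3", "MT-CO3",
             "CYTOCHROMECOXIDASESUBUNIT3", "CYTOCHROMECOXIDASESUBUNITIII"),
    cob = c("COB", "CYTB", "CYB", "CYTOCHROMEB", "MT-CYB", "COBB"),
    atp6 = c("ATP6", "ATPASE6", "ATPASESUBUNIT6", "ATPSYNTHASEF0SUBUNIT6",
             "ATPSYNTHASESUBUNIT6", "MT-ATP6"),
    atp8 = c("ATP8", "ATPASE8", "ATPASESUBUNIT8", "ATPSYNTHASEF0SUBUNIT8",
             "ATPSYNTHASESUBUNIT8", "MT-ATP8"),
    rrnS = c("RRNS", "12S", "12SRRNA", "12SRIBOSOMALRNA", "S-RRNA", "SRRNA",
             "SMALLSUBUNITRIBOSOMALRNA", "RNS", "MT-RNR1", "12SRNA"),
    rrnL = c("RRNL", "16S", "16SRRNA", "16SRIBOSOMALRNA", "L-RRNA", "LRRNA",
             "LARGESUBUNITRIBOSOMALRNA", "RNL", "MT-RNR2", "16SRNA"),
    CR = c("CR", "D-LOOP", "DLOOP", "CONTROLREGION", "PUTATIVECONTROLREGION",
           "MITOCHONDRIALCONTROLREGION")
  )
  out <- character()
  for (canon in names(syn)) out[syn[[canon]]] <- canon
  out
})

# anticodons of the duplicated Leu/Ser tRNAs (DNA alphabet)
LS_ANTICODONS <- c(TAA = "L1", TAG = "L2", TGA = "S1", GCT = "S2")

#' Normalise a raw gene or product name to the canonical vocabulary
#'
#' Case-insensitive lookup through an explicit synonym table covering the
#' naming variants found in deposited mitogenome records (ND1/NADH1/nad1,
#' COX1/COI/CO1, CYTB/cob, D-loop/control region, ...). tRNAs are reduced to
#' their one-letter amino-acid code; the duplicated leucine and serine tRNAs
#' are split into L1/L2 and S1/S2 when the name or the `anticodon` argument
#' identifies the isoacceptor (L1 = Leu(UUR), L2 = Leu(CUN), S1 = Ser(UCN),
#' S2 = Ser(AGY)). Unknown names map to `"OTHER"`; unresolved Leu/Ser copies
#' map to the provisional labels `"L?"`/`"S?"` for positional resolution by
#' the readers.
#'
#' @param raw Character vector of raw names.
#' @param anticodon Optional character vector of anticodon triplets (DNA or
#'   RNA alphabet), recycled to the length of `raw`.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' canonical_label(c("ND2", "COI", "D-loop", "tRNA-Phe", "unknown orf"))
canonical_label <- function(raw, anticodon = NULL) {
  if (!length(raw)) return(character())
  if (is.null(anticodon)) anticodon <- NA_character_
  anticodon <- rep_len(as.character(anticodon), length(raw))
  vapply(seq_along(raw), function(i) {
    canonical_label_one(raw[[i]], anticodon[[i]])
  }, character(1))
}

canonical_label_one <- function(raw, anticodon = NA_character_) {
  if (is.na(raw) || !nzchar(raw)) return("OTHER")
  key <- str_to_upper(trimws(raw))
  squash <- gsub("[ _]", "", key)
  hit <- unname(GENE_SYNONYMS[squash])
  if (!is.na(hit)) return(hit)
  # tRNA forms: "tRNA-Phe", "trnF", "tRNA-Leu (UUR)", "trnL2", "trnL(UAA)"
  if (str_detect(key, "TRN")) {
    iso <- trna_isoacceptor(key)
    aa <- trna_amino_acid(key)
    if (!is.na(aa)) {
      if (aa %in% c("L", "S")) {
        if (!is.na(iso)) return(paste0(aa, iso))
        byac <- ls_by_anticodon(key, anticodon)
        if (!is.na(byac) && startsWith(byac, aa)) return(byac)
        return(paste0(aa, "?"))
      }
      if (aa %in% CANONICAL_TRNAS) return(aa)
    }
  }
  "OTHER"
}

trna_amino_acid <- function(key) {
  m <- regmatches(key, regexpr("TRNA?[-_ ]?(ALA|ARG|ASN|ASP|CYS|GLN|GLU|GLY|HIS|ILE|LEU|LYS|MET|PHE|PRO|SER|THR|TRP|TYR|VAL)", key))
  if (length(m)) {
    aa3 <- str_sub(m, -3L)
    return(unname(AA3_TO_1[[aa3]]))
  }
  m <- regmatches(key, regexpr("TRN-?([A-Z])[0-9]?\\b", key))
  if (length(m)) {
    letter <- str_sub(gsub("[^A-Z0-9]", "", gsub("^TRN", "", m)), 1L, 1L)
    if (letter %in% AA3_TO_1) return(letter)
  }
  NA_character_
}

trna_isoacceptor <- function(key) {
  if (str_detect(key, "UUR|TTR|\\(UUA\\)|\\(TAA\\)|TRNL1|TRN-?L1|LEU1")) return("1")
  if (str_detect(key, "CUN|CTN|\\(UAG\\)|\\(TAG\\)|TRNL2|TRN-?L2|LEU2")) return("2")
  if (str_detect(key, "UCN|TCN|\\(UGA\\)|\\(TGA\\)|TRNS1|TRN-?S1|SER1")) return("1")
  if (str_detect(key, "AGY|AGN|\\(GCU\\)|\\(GCT\\)|TRNS2|TRN-?S2|SER2")) return("2")
  NA_character_
}

ls_by_anticodon <- function(key, anticodon) {
  ac <- anticodon
  if (is.na(ac)) {
    m <- regmatches(key, regexpr("\\(([ACGUT]{3})\\)", key))
    if (length(m)) ac <- gsub("[()]", "", m)
  }
  if (is.na(ac)) return(NA_character_)
  ac <- chartr("U", "T", str_to_upper(ac))
  if (ac %in% names(LS_ANTICODONS)) unname(LS_ANTICODONS[[ac]]) else NA_character_
}

#' @noRd
#' Feature type implied by a canonical label.
label_ftype <- function(label) {
  dplyr::case_when(
    label %in% CANONICAL_PCGS ~ "PCG",
    label %in% CANONICAL_RRNAS ~ "rRNA",
    label %in% c(CANONICAL_TRNAS, "L?", "S?") ~ "tRNA",
    label == "CR" ~ "CR",
    TRUE ~ "other"
  )
}

# Resolve provisional "L?"/"S?" tRNA labels left by canonical_label():
# first by position next to template neighbours (L1 follows rrnL; S1 follows
# cox1; S2 precedes L2 which precedes nad5), then by order of appearance.
resolve_ls_paralogs <- function(features) {
  for (aa in c("L", "S")) {
    prov <- paste0(aa, "?")
    idx <- which(features$label == prov)
    if (!length(idx)) next
    taken <- intersect(paste0(aa, c("1", "2")), features$label)
    free <- setdiff(paste0(aa, c("1", "2")), taken)
    for (i in idx) {
      if (!length(free)) break
      guess <- ls_positional_guess(features, i, aa)
      pick <- if (!is.na(guess) && guess %in% free) guess else free[[1]]
      features$label[i] <- pick
      free <- setdiff(free, pick)
    }
    features$label[features$label == prov] <- "OTHER"
  }
  features
}

ls_positional_guess <- function(features, i, aa) {
  nb <- function(j) features$label[((j - 1) %% nrow(features)) + 1]
  prev <- nb(i - 1); nxt <- nb(i + 1)
  if (aa == "L") {
    if (prev == "rrnL" || nxt == "nad1") return("L1")
    if (prev == "S2" || nxt == "nad5") return("L2")
  } else {
    if (prev == "cox1" || nxt == "D") return("S1")
    if (prev == "H" || nxt == "L2") return("S2")
  }
  NA_character_
}
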