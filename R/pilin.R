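# Type IV aromatic pilin (T4AP) candidates: short pilins whose mature
# peptide is dense in aromatic residues, implicated in long-range electron
# conduction. They carry no heme motifs, so they are reported separately
# and never count toward neighborhood heme totals.

#' Pilin detection parameters
#'
#' The rule is a transparent Geobacter-PilA-like stand-in: a class-III
#' (prepilin peptidase) processing site `G-[FMLIV]-x-x-x-E` near the
#' N-terminus, mature-peptide length limits, and a minimum aromatic density
#' on the mature peptide.
#'
#' @param min_length,max_length Full-protein length gate in residues
#'   (defaults 50 and 200 — pilins are small).
#' @param motif_search_start,motif_search_end Residue range in which the
#'   `G` of the processing site may sit (defaults 2 and 40).
#' @param aromatic_min Minimum fraction of F/Y/W/H in the mature peptide
#'   (default 0.09).
#' @return A list of class `pilin_params`.
#' @export
pilin_params <- function(min_length = 50L, max_length = 200L,
                         motif_search_start = 2L, motif_search_end = 40L,
                         aromatic_min = 0.09) {
  structure(
    list(min_length = as.integer(min_length),
         max_length = as.integer(max_length),
         motif_search_start = as.integer(motif_search_start),
         motif_search_end = as.integer(motif_search_end),
         aromatic_min = aromatic_min),
    class = "pilin_params"
  )
}

#' Flag type IV aromatic pilin candidates
#'
#' Three gates per protein: (1) `length_ok` — full length within
#' `[min_length, max_length]`; (2) `motif_ok` — a prepilin-peptidase site
#' `G-[FMLIV]-x-x-x-E` with the `G` within the N-terminal search range
#' (cleavage after the `G`, so `mature_start` is the index of the
#' hydrophobic residue that begins the mature pilin); (3) aromatic density —
#' the fraction of F/Y/W/H in the mature peptide at least `aromatic_min`.
#' A candidate passes all three.
#'
#' @param genes A data frame with columns `gene_id` and `protein_seq`
#'   (an `assembly_id` column is carried through if present).
#' @param params A [pilin_params()].
#' @return A tibble with one row per gene: `gene_id`, `length`,
#'   `length_ok`, `motif_ok`, `mature_start` (NA when no site),
#'   `aromatic_fraction` (NA when no site), `is_candidate`.
#' @export
detect_t4ap <- function(genes, params = pilin_params()) {
  stopifnot(all(c("gene_id", "protein_seq") %in% names(genes)))
  out <- map2(genes$gene_id, genes$protein_seq, function(id, seq) {
    n <- nchar(seq)
    length_ok <- n >= params$min_length && n <= params$max_length
    m <- prepilin_site(seq, params)
    motif_ok <- !is.na(m)
    mature_start <- if (motif_ok) m + 1L else NA_integer_
    aromatic_fraction <- NA_real_
    if (motif_ok && mature_start <= n) {
      mature <- substr(seq, mature_start, n)
      aromatic_fraction <- str_count(mature, "[FYWH]") / nchar(mature)
    }
    tibble(
      gene_id = id, length = n, length_ok = length_ok, motif_ok = motif_ok,
      mature_start = mature_start, aromatic_fraction = aromatic_fraction,
      is_candidate = length_ok && motif_ok &&
        !is.na(aromatic_fraction) && aromatic_fraction >= params$aromatic_min
    )
  })
  out <- bind_rows(out)
  if ("assembly_id" %in% names(genes)) {
    out <- mutate(out, assembly_id = genes$assembly_id, .before = 1L)
  }
  out
}

# first G in the search range followed by [FMLIV] and an E five residues
# after the G (the canonical G|[FMLIV]xxxE site); returns the G index or NA
prepilin_site <- function(seq, params) {
  n <- nchar(seq)
  lo <- params$motif_search_start
  hi <- min(params$motif_search_end, n - 5L)
  if (hi < lo) return(NA_integer_)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (g in lo:hi) {
    if (res[g] == "G" && res[g + 1L] %in% c("F", "M", "L", "I", "V") &&
        res[g + 5L] == "E") {
      return(g)
    }
  }
  NA_integer_
}
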