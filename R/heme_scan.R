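# c-type heme-binding motif detection. Hemes attach covalently at
# CXXCH-family sites; the scanner counts non-overlapping motif occurrences
# per protein under a greedy left-to-right policy (one heme cannot serve two
# attachment sites) and classifies proteins by count.

#' Heme motif scan configuration
#'
#' Motif templates use uppercase letters for literal residues and lowercase
#' `x` for a wildcard. Defaults are the canonical `CxxCH` heme attachment
#' site, its `Cx3CH` / `Cx4CH` spacing variants, and the `CxxCK` variant —
#' the motif families the c-type cytochrome literature documents. Each
#' template must start with `C`, contain a second `C`, end in `H` or `K`,
#' and have 2–4 wildcards between the cysteines.
#'
#' @param motif_patterns Character vector of motif templates.
#' @param mhc_min_hemes Minimum motif count for a protein to count as a
#'   multi-heme cytochrome (MHC). Default 3: excludes the ubiquitous mono-
#'   and diheme cytochromes.
#' @param heme_rich_min Minimum motif count for the heme-rich flag
#'   (default 4).
#' @param high_heme_min Minimum motif count for the high-heme flag
#'   (default 11, i.e. strictly more than 10 motifs).
#' @return A list of class `heme_config`.
#' @export
heme_config <- function(motif_patterns = c("CxxCH", "CxxxCH", "CxxxxCH", "CxxCK"),
                        mhc_min_hemes = 3L,
                        heme_rich_min = 4L,
                        high_heme_min = 11L) {
  stopifnot(mhc_min_hemes >= 1L, heme_rich_min >= 1L, high_heme_min >= 1L,
            length(motif_patterns) >= 1L)
  ok <- grepl("^C(x{2,4})C[HK]$", motif_patterns)
  if (!all(ok)) {
    abort(sprintf(
      "Invalid motif template(s): %s (expected C, 2-4 'x' wildcards, C, then H or K).",
      paste(motif_patterns[!ok], collapse = ", ")
    ))
  }
  structure(
    list(
      motif_patterns = motif_patterns,
      mhc_min_hemes = as.integer(mhc_min_hemes),
      heme_rich_min = as.integer(heme_rich_min),
      high_heme_min = as.integer(high_heme_min)
    ),
    class = "heme_config"
  )
}

# templates ordered shortest-first, ties broken by config order, so the
# canonical CxxCH wins over longer-spacer variants at the same start
ordered_templates <- function(config) {
  config$motif_patterns[order(nchar(config$motif_patterns),
                              seq_along(config$motif_patterns))]
}

#' Scan one protein sequence for heme-binding motifs
#'
#' Greedy left-to-right scan: at each residue index the templates are tried
#' shortest-first (ties in configuration order); on a match the hit is
#' recorded and scanning resumes at the residue after the matched span, so
#' hits never overlap. Wildcard positions accept any residue including
#' `X`/`U`; the anchor positions require literal `C` and `H`/`K`, which
#' `X`/`U` never satisfy.
#'
#' @param protein_seq A single uppercase amino-acid string (no `*`).
#' @param config A [heme_config()].
#' @return A tibble of hits with columns `start_pos` (1-based residue
#'   index), `matched_text`, `template`; zero rows when nothing matches.
#' @examples
#' scan_heme_motifs("MCAACHAA")
#' @export
scan_heme_motifs <- function(protein_seq, config = heme_config()) {
  templates <- ordered_templates(config)
  n <- nchar(protein_seq)
  res <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
  tmpl_last <- substr(templates, nchar(templates), nchar(templates))
  tmpl_len <- nchar(templates)

  starts <- integer(0); texts <- character(0); tmpls <- character(0)
  i <- 1L
  while (i <= n) {
    if (res[i] == "C") {
      for (t in seq_along(templates)) {
        len <- tmpl_len[t]
        j <- i + len - 1L
        if (j > n) next
        # second C sits two before the terminal anchor
        if (res[j - 1L] == "C" && res[j] == tmpl_last[t]) {
          starts <- c(starts, i)
          texts <- c(texts, substr(protein_seq, i, j))
          tmpls <- c(tmpls, templates[t])
          i <- j  # +1 below
          break
        }
      }
    }
    i <- i + 1L
  }
  tibble(start_pos = starts, matched_text = texts, template = tmpls)
}

#' Scan a gene table for heme-binding motifs
#'
#' Applies [scan_heme_motifs()] to every protein and classifies each by
#' count: `is_mhc` (>= `mhc_min_hemes`), `is_heme_rich`
#' (>= `heme_rich_min`), `is_high_heme` (>= `high_heme_min`).
#'
#' @param genes A data frame with columns `gene_id` and `protein_seq` (a gene
#'   table from [assembly_from_prodigal()] / [read_gff_cds()], or any tibble
#'   with those columns).
#' @param config A [heme_config()].
#' @return A tibble with one row per gene: `gene_id`, `hits` (list-column of
#'   hit tibbles), `heme_count`, `is_mhc`, `is_heme_rich`, `is_high_heme`.
#' @export
scan_hemes <- function(genes, config = heme_config()) {
  stopifnot(all(c("gene_id", "protein_seq") %in% names(genes)))
  hits <- map(genes$protein_seq, scan_heme_motifs, config = config)
  ann <- tibble(
    gene_id = genes$gene_id,
    hits = hits,
    heme_count = map_int(hits, nrow)
  )
  classify_hemes(ann, config)
}

#' (Re)compute heme classification flags from counts
#'
#' Threshold comparisons on `heme_count`; useful to re-gate an existing
#' annotation under different thresholds without rescanning.
#'
#' @param annotations Tibble with a `heme_count` column.
#' @param config A [heme_config()].
#' @return `annotations` with `is_mhc`, `is_heme_rich`, `is_high_heme`
#'   columns set from `config`.
#' @export
classify_hemes <- function(annotations, config = heme_config()) {
  stopifnot("heme_count" %in% names(annotations))
  annotations |>
    mutate(
      is_mhc = .data$heme_count >= config$mhc_min_hemes,
      is_heme_rich = .data$heme_count >= config$heme_rich_min,
      is_high_heme = .data$heme_count >= config$high_heme_min
    )
}
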