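# Contig-local gene neighborhoods around exported multi-heme cytochrome
# seeds, with the three inclusion criteria: an MHC carrying a signal
# peptide, at least one heme-rich (>= 4 hemes) MHC, and at least 15 hemes
# summed over the whole cluster.

#' Neighborhood construction and filtering configuration
#'
#' @param max_intergenic_bp Maximum gap in bp between consecutive genes
#'   (start of the next minus end of the previous) for them to chain into
#'   one neighborhood. Default 500, a standard operon-context heuristic.
#' @param max_rank_gap Rank adjacency required to chain; with the default 1
#'   only consecutive genes along the contig chain (the only supported
#'   mode — the key is carried for interface completeness).
#' @param min_cluster_hemes Minimum combined heme count across the
#'   neighborhood (default 15).
#' @param require_sp_mhc Require at least one MHC with a signal peptide
#'   (default TRUE).
#' @param require_heme_rich Require at least one heme-rich MHC
#'   (default TRUE).
#' @return A list of class `neighborhood_config`.
#' @export
neighborhood_config <- function(max_intergenic_bp = 500L, max_rank_gap = 1L,
                                min_cluster_hemes = 15L,
                                require_sp_mhc = TRUE,
                                require_heme_rich = TRUE) {
  stopifnot(max_intergenic_bp >= 0L, min_cluster_hemes >= 1L)
  structure(
    list(max_intergenic_bp = as.integer(max_intergenic_bp),
         max_rank_gap = as.integer(max_rank_gap),
         min_cluster_hemes = as.integer(min_cluster_hemes),
         require_sp_mhc = isTRUE(require_sp_mhc),
         require_heme_rich = isTRUE(require_heme_rich)),
    class = "neighborhood_config"
  )
}

#' Assemble gene neighborhoods around exported MHC seeds
#'
#' Seed genes are proteins that are MHCs (`is_mhc`) and exported
#' (`localization == "exported"`). On each contig, consecutive genes chain
#' while the intergenic distance (next start minus previous end) stays
#' within `max_intergenic_bp`; every maximal chain containing at least one
#' seed becomes a neighborhood. Neighborhoods never span contigs, are
#' pairwise disjoint, and every seed belongs to exactly one. Chaining is
#' strand-agnostic: porin-cytochrome modules routinely include divergently
#' transcribed accessory genes.
#'
#' @param genes A gene table (see [assembly_from_prodigal()]).
#' @param annotations Heme annotations from [scan_hemes()].
#' @param localizations Localization calls from [predict_localization()] or
#'   [merge_localization()].
#' @param config A [neighborhood_config()].
#' @return A tibble with one row per neighborhood: `assembly_id`,
#'   `neighborhood_id`, `contig`, `first_gene_start`, `last_gene_end`,
#'   `n_genes`, and a `members` list-column of per-gene tibbles (gene id,
#'   coordinates, heme count and flags, localization). Aggregate criteria
#'   columns are filled by [apply_criteria()].
#' @export
build_neighborhoods <- function(genes, annotations, localizations,
                                config = neighborhood_config()) {
  missing_ann <- setdiff(genes$gene_id, annotations$gene_id)
  if (length(missing_ann) > 0L) {
    abort(sprintf("Gene(s) without a heme annotation: %s",
                  paste(head(missing_ann, 5), collapse = ", ")))
  }
  missing_loc <- setdiff(genes$gene_id, localizations$gene_id)
  if (length(missing_loc) > 0L) {
    abort(sprintf("Gene(s) without a localization call: %s",
                  paste(head(missing_loc, 5), collapse = ", ")))
  }
  members <- genes |>
    left_join(
      annotations[, c("gene_id", "heme_count", "is_mhc", "is_heme_rich",
                      "is_high_heme")],
      by = "gene_id"
    ) |>
    left_join(
      localizations[, c("gene_id", "has_signal_peptide", "localization")],
      by = "gene_id"
    ) |>
    arrange(.data$assembly_id, .data$contig, .data$rank)

  members <- members |>
    group_by(.data$assembly_id, .data$contig) |>
    mutate(
      gap_bp = .data$start - dplyr::lag(.data$end),
      new_chain = is.na(.data$gap_bp) | .data$gap_bp > config$max_intergenic_bp,
      chain = cumsum(.data$new_chain)
    ) |>
    ungroup()

  chains <- members |>
    mutate(seed = .data$is_mhc & .data$localization == "exported") |>
    group_by(.data$assembly_id, .data$contig, .data$chain) |>
    filter(any(.data$seed)) |>
    ungroup()

  if (nrow(chains) == 0L) return(empty_neighborhoods())

  nb <- chains |>
    tidyr::nest(members = -all_of(c("assembly_id", "contig", "chain"))) |>
    arrange(.data$assembly_id, .data$contig,
            map_int(.data$members, ~ min(.x$start))) |>
    mutate(
      neighborhood_id = sprintf("%s_nbh_%03d", .data$assembly_id,
                                row_number()),
      first_gene_start = map_int(.data$members, ~ min(.x$start)),
      last_gene_end = map_int(.data$members, ~ max(.x$end)),
      n_genes = map_int(.data$members, nrow)
    ) |>
    select(all_of(c("assembly_id", "neighborhood_id", "contig",
                    "first_gene_start", "last_gene_end", "n_genes",
                    "members")))
  nb
}

empty_neighborhoods <- function() {
  tibble(
    assembly_id = character(), neighborhood_id = character(),
    contig = character(), first_gene_start = integer(),
    last_gene_end = integer(), n_genes = integer(), members = list()
  )
}

#' Apply the inclusion criteria to neighborhoods
#'
#' Fills the aggregate columns and evaluates the three gates: (1) at least
#' one MHC with a signal peptide; (2) at least one heme-rich MHC; (3) at
#' least `min_cluster_hemes` hemes summed over every member protein —
#' hemes in cytoplasmic members still count toward the total. Each gate is
#' individually toggleable; `criteria_failed` lists every failed gate and
#' `passes` is true exactly when it is empty.
#'
#' @param neighborhoods Tibble from [build_neighborhoods()].
#' @param config A [neighborhood_config()].
#' @return The neighborhoods tibble with columns `total_hemes`, `n_mhc`,
#'   `n_heme_rich`, `has_sp_mhc`, `accessory_genes` (members below the MHC
#'   threshold), `criteria_failed` (list-column), `passes`.
#' @export
apply_criteria <- function(neighborhoods, config = neighborhood_config()) {
  if (nrow(neighborhoods) == 0L) {
    out <- neighborhoods
    out$total_hemes <- integer(0); out$n_mhc <- integer(0)
    out$n_heme_rich <- integer(0); out$has_sp_mhc <- logical(0)
    out$accessory_genes <- list(); out$criteria_failed <- list()
    out$passes <- logical(0)
    return(out)
  }
  neighborhoods |>
    mutate(
      total_hemes = map_int(.data$members, ~ sum(.x$heme_count)),
      n_mhc = map_int(.data$members, ~ sum(.x$is_mhc)),
      n_heme_rich = map_int(.data$members, ~ sum(.x$is_heme_rich)),
      has_sp_mhc = map_lgl(.data$members,
                           ~ any(.x$is_mhc & .x$has_signal_peptide)),
      accessory_genes = map(.data$members, ~ .x$gene_id[!.x$is_mhc]),
      criteria_failed = pmap(
        list(.data$has_sp_mhc, .data$n_heme_rich, .data$total_hemes),
        function(sp, hr, th) {
          failed <- character(0)
          if (config$require_sp_mhc && !sp) failed <- c(failed, "sp_mhc")
          if (config$require_heme_rich && hr < 1L)
            failed <- c(failed, "heme_rich")
          if (th < config$min_cluster_hemes)
            failed <- c(failed, "total_hemes")
          failed
        }
      ),
      passes = map_int(.data$criteria_failed, length) == 0L
    )
}

#' Summarize an assembly's passing neighborhoods
#'
#' Counts are taken over passing neighborhoods only: the number passing, the
#' hemes they contain, and how many member proteins carry the high-heme
#' flag (more than 10 motifs by default).
#'
#' @param neighborhoods Tibble from [apply_criteria()].
#' @return A tibble with one row per assembly: `assembly_id`,
#'   `n_neighborhoods_pass`, `total_hemes_pass`, `n_high_heme_proteins`.
#' @export
summarize_assembly <- function(neighborhoods) {
  if (nrow(neighborhoods) == 0L) {
    return(tibble(assembly_id = character(),
                  n_neighborhoods_pass = integer(),
                  total_hemes_pass = integer(),
                  n_high_heme_proteins = integer()))
  }
  neighborhoods |>
    group_by(.data$assembly_id) |>
    summarise(
      n_neighborhoods_pass = sum(.data$passes),
      total_hemes_pass = sum(.data$total_hemes[.data$passes]),
      n_high_heme_proteins = sum(map_int(
        .data$members[.data$passes], ~ sum(.x$is_high_heme)
      )),
      .groups = "drop"
    )
}
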