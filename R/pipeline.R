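# End-to-end orchestration: scan one annotated genome for heme motifs,
# localization, neighborhoods and pilins (scan_genome / run_scan), and
# cluster discovered MHCs into families (run_families). File-level entry
# points write the deterministic TSV reports and echo the resolved
# configuration for reproducibility.

#' Scan a gene table end to end
#'
#' Runs the full in-memory pipeline: heme-motif scan, localization
#' (built-in heuristic, optionally overridden by external calls),
#' neighborhood construction and criteria, pilin detection, and the
#' per-assembly summary.
#'
#' @param genes A gene table from [assembly_from_prodigal()],
#'   [read_gff_cds()], or [simulate_assembly()].
#' @param heme A [heme_config()].
#' @param loc_params A [localization_params()].
#' @param nbh A [neighborhood_config()].
#' @param pilin A [pilin_params()], or `NULL` to skip pilin detection.
#' @param external_localization Optional tibble from
#'   [parse_phobius_short()]; merged with policy `external_wins`.
#' @return An object of class `mhc_scan`: a list with tibbles `proteins`
#'   (gene table + heme + localization columns), `neighborhoods` (criteria
#'   applied), `pilins`, `summary`, and the configurations used.
#' @examples
#' sim <- simulate_assembly(
#'   list(cluster_spec(c(10, 10, 0), c(TRUE, TRUE, FALSE))),
#'   n_decoy_genes = 4, seed = 7
#' )
#' res <- scan_genome(sim$genes)
#' res$neighborhoods[, c("neighborhood_id", "total_hemes", "passes")]
#' @export
scan_genome <- function(genes,
                        heme = heme_config(),
                        loc_params = localization_params(),
                        nbh = neighborhood_config(),
                        pilin = pilin_params(),
                        external_localization = NULL) {
  annotations <- scan_hemes(genes, heme)
  builtin <- predict_localization(genes, loc_params)
  localizations <- merge_localization(builtin, external_localization,
                                      gene_ids = genes$gene_id)
  neighborhoods <- build_neighborhoods(genes, annotations, localizations, nbh) |>
    apply_criteria(nbh)
  pilins <- if (is.null(pilin)) NULL else detect_t4ap(genes, pilin)
  proteins <- genes |>
    left_join(annotations[, c("gene_id", "heme_count", "is_mhc",
                              "is_heme_rich", "is_high_heme")],
              by = "gene_id") |>
    left_join(localizations[, c("gene_id", "has_signal_peptide", "n_tm",
                                "localization", "source")],
              by = "gene_id")
  structure(
    list(
      proteins = proteins,
      neighborhoods = neighborhoods,
      pilins = pilins,
      summary = summarize_assembly(neighborhoods),
      config = list(heme = heme, localization = loc_params,
                    neighborhood = nbh, pilin = pilin)
    ),
    class = "mhc_scan"
  )
}

#' @export
print.mhc_scan <- function(x, ...) {
  cat("<mhc_scan>\n")
  cat(sprintf("  proteins:        %d (%d MHC, %d heme-rich, %d high-heme)\n",
              nrow(x$proteins), sum(x$proteins$is_mhc),
              sum(x$proteins$is_heme_rich), sum(x$proteins$is_high_heme)))
  cat(sprintf("  neighborhoods:   %d (%d passing)\n",
              nrow(x$neighborhoods), sum(x$neighborhoods$passes)))
  if (!is.null(x$pilins)) {
    cat(sprintf("  pilin candidates: %d\n", sum(x$pilins$is_candidate)))
  }
  invisible(x)
}

#' Tidy the neighborhoods of a scan result
#'
#' @param x An `mhc_scan` object.
#' @param ... Unused.
#' @return The neighborhoods tibble without list-columns, one row per
#'   neighborhood.
#' @export
tidy.mhc_scan <- function(x, ...) {
  x$neighborhoods |>
    mutate(gene_ids = map_chr(.data$members, ~ paste(.x$gene_id,
                                                     collapse = ",")),
           criteria_failed = map_chr(.data$criteria_failed, paste,
                                     collapse = ",")) |>
    select(-all_of(c("members")))
}

#' One-row summary of a scan result
#'
#' @param x An `mhc_scan` object.
#' @param ... Unused.
#' @return A one-row tibble: protein, MHC, heme-rich, high-heme,
#'   neighborhood and passing-neighborhood counts plus total passing hemes.
#' @export
glance.mhc_scan <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$proteins),
    n_mhc = sum(x$proteins$is_mhc),
    n_heme_rich = sum(x$proteins$is_heme_rich),
    n_high_heme = sum(x$proteins$is_high_heme),
    n_neighborhoods = nrow(x$neighborhoods),
    n_pass = sum(x$neighborhoods$passes),
    total_hemes_pass = sum(x$neighborhoods$total_hemes[x$neighborhoods$passes]),
    n_pilin_candidates = if (is.null(x$pilins)) NA_integer_
                         else sum(x$pilins$is_candidate)
  )
}

#' Run the scan pipeline on files and write reports
#'
#' Reads a protein FASTA (Prodigal-dialect headers) and, when given, a GFF3
#' annotation (the GFF wins over Prodigal headers) and external Phobius
#' calls; runs [scan_genome()]; writes `proteins.tsv`, `neighborhoods.tsv`,
#' `pilins.tsv`, `summary.tsv` and a `run_config.yaml` echo into `out_dir`.
#' Reports are byte-identical across reruns on identical input.
#'
#' @param faa Path to the protein FASTA.
#' @param gff Optional path to a GFF3 file with CDS rows.
#' @param phobius Optional path to a Phobius short-format table.
#' @param out_dir Output directory (created if needed).
#' @param assembly_id Assembly label (default: FASTA basename).
#' @inheritParams scan_genome
#' @return The `mhc_scan` object, invisibly.
#' @export
run_scan <- function(faa, gff = NULL, phobius = NULL, out_dir,
                     assembly_id = NULL,
                     heme = heme_config(),
                     loc_params = localization_params(),
                     nbh = neighborhood_config(),
                     pilin = pilin_params()) {
  assembly_id <- assembly_id %||% sub("\\.[^.]*$", "", basename(faa))
  proteins <- read_protein_fasta(faa)
  genes <- if (!is.null(gff)) {
    read_gff_cds(gff, proteins, assembly_id = assembly_id)
  } else {
    assembly_from_prodigal(proteins, assembly_id = assembly_id)
  }
  external <- if (!is.null(phobius)) parse_phobius_short(phobius) else NULL
  res <- scan_genome(genes, heme = heme, loc_params = loc_params, nbh = nbh,
                     pilin = pilin, external_localization = external)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_tsv(res$proteins, file.path(out_dir, "proteins.tsv"))
  write_neighborhood_tsv(res$neighborhoods,
                         file.path(out_dir, "neighborhoods.tsv"))
  if (!is.null(res$pilins)) {
    write_pilin_tsv(res$pilins, file.path(out_dir, "pilins.tsv"))
  }
  write_report_tsv(res$summary, file.path(out_dir, "summary.tsv"))
  echo_config(res$config, inputs = list(faa = faa, gff = gff,
                                        phobius = phobius),
              path = file.path(out_dir, "run_config.yaml"))
  invisible(res)
}

echo_config <- function(config, inputs, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  y <- list(inputs = inputs[!vapply(inputs, is.null, logical(1))],
            config = strip(config[!vapply(config, is.null, logical(1))]))
  writeLines(yaml::as.yaml(y), path)
  invisible(path)
}

#' Cluster exported MHCs into families and export alignments
#'
#' Takes a scan result (or any protein tibble with `is_mhc`,
#' `localization` and `protein_seq` columns), keeps proteins that are MHCs
#' and exported, clusters them greedily, applies the family-size filter,
#' and writes `families.tsv` plus masked Stockholm / aligned-FASTA files
#' for eligible families.
#'
#' @param proteins An `mhc_scan` object or its `proteins` tibble (several
#'   scans can be row-bound to cluster across assemblies).
#' @param out_dir Output directory (created if needed).
#' @param config A [family_config()].
#' @return A tibble of families (with `hmm_eligible` and `mean_hemes`),
#'   invisibly. Zero qualifying proteins yields an empty table plus a
#'   notice, not an error.
#' @export
run_families <- function(proteins, out_dir, config = family_config()) {
  if (inherits(proteins, "mhc_scan")) proteins <- proteins$proteins
  qual <- proteins |>
    filter(.data$is_mhc, .data$localization == "exported")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(qual) == 0L) {
    inform("No exported MHC proteins; families.tsv will be empty.")
    fam <- tibble(family_id = character(), centroid_id = character(),
                  member_ids = list(), size = integer(),
                  hmm_eligible = logical(), mean_hemes = double())
    write_families_tsv(fam, file.path(out_dir, "families.tsv"))
    return(invisible(fam))
  }
  fam <- greedy_cluster(qual, config) |>
    filter_families(config$min_family_size) |>
    mutate(mean_hemes = map_dbl(.data$member_ids, function(ids) {
      mean(qual$heme_count[match(ids, qual$gene_id)])
    }))
  write_families_tsv(fam, file.path(out_dir, "families.tsv"))
  export_family_alignments(fam, qual, out_dir, config)
  invisible(fam)
}
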