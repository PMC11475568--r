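# Synthetic assemblies with planted MHC clusters, decoys and pilins. The
# generator is constructive: heme counts, export status and neighborhood
# membership are forced analytically (restricted background alphabet plus
# rejection checks against the scanning and localization rules), so the
# truth table is exact, not probabilistic.

# background alphabet excludes C/H/K (no accidental heme motifs), F/Y/W (no
# accidental aromatic density) and the strongly hydrophobic L/I/V/M/F (no
# accidental hydrophobic segments beyond the planted cassette)
SYNTH_BACKGROUND <- c("A", "G", "S", "T", "P", "D", "E", "N", "Q")

# signal-peptide cassette the builtin heuristic accepts: charged n-region
# then a 20-Leu hydrophobic core
SP_CASSETTE <- paste0("MKK", strrep("L", 20))

#' Generate a synthetic protein with an exact heme-motif count
#'
#' Builds a protein whose greedy heme scan returns exactly `heme_count`
#' hits: `CxxCH` motifs (wildcards drawn from the background alphabet) are
#' planted at randomized positions separated by at least 5 background
#' residues, on a background that contains no C, H or K. If `exported`, a
#' signal-peptide cassette (`MKK` + 20 Leu) is prepended and the built-in
#' localization heuristic is guaranteed to call the protein exported;
#' otherwise the protein is guaranteed cytoplasmic. Both guarantees are
#' verified by rejection sampling against the package's own scanners.
#'
#' @param heme_count Number of motifs to plant (>= 0).
#' @param exported Prepend the signal-peptide cassette?
#' @param length Total protein length; must be at least
#'   `5*heme_count + 30` (plus 23 for the cassette when exported).
#' @param rng An R random-number state is used; call [set.seed()] upstream
#'   or pass `seed` for per-protein determinism.
#' @param seed Optional integer seed applied locally to this protein.
#' @return A single protein sequence string.
#' @export
make_protein <- function(heme_count, exported = FALSE, length = NULL,
                         seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stopifnot(heme_count >= 0L)
  sp <- if (exported) SP_CASSETTE else ""
  min_body <- 5L * heme_count + 6L * max(heme_count - 1L, 0L) + 10L
  if (is.null(length)) length <- max(5L * heme_count + 60L, min_body + 30L) + nchar(sp)
  body_len <- length - nchar(sp)
  if (body_len < min_body) {
    abort(sprintf(
      "length %d infeasible for %d motifs%s (need body >= %d).",
      length, heme_count, if (exported) " + signal cassette" else "",
      min_body + nchar(sp)
    ))
  }
  for (attempt in 1:50) {
    body <- build_motif_body(heme_count, body_len)
    seq <- paste0(sp, body)
    ann <- scan_heme_motifs(seq)
    loc <- localize_one("x", seq, localization_params())
    ok_heme <- nrow(ann) == heme_count
    ok_loc <- loc$localization == (if (exported) "exported" else "cytoplasmic")
    if (ok_heme && ok_loc) return(seq)
  }
  abort("Rejection sampling failed to produce a conforming protein.")
}

build_motif_body <- function(heme_count, body_len) {
  bg <- function(n) paste(sample(SYNTH_BACKGROUND, n, replace = TRUE),
                          collapse = "")
  if (heme_count == 0L) return(bg(body_len))
  motifs <- vapply(seq_len(heme_count), function(i) {
    paste0("C", bg(2L), "CH")
  }, character(1))
  # gaps: >= 5 background residues between motifs, >= 1 at the start so the
  # motif never abuts the signal cassette
  n_gap <- heme_count + 1L
  spare <- body_len - 5L * heme_count - 5L * (heme_count - 1L) - 1L
  extra <- if (spare > 0L) {
    tabulate(sample.int(n_gap, spare, replace = TRUE), nbins = n_gap)
  } else rep(0L, n_gap)
  gap_len <- c(1L, rep(5L, heme_count - 1L), 0L)[seq_len(n_gap)]
  gap_len <- gap_len + extra
  pieces <- character(0)
  for (i in seq_len(heme_count)) {
    pieces <- c(pieces, bg(gap_len[i]), motifs[i])
  }
  paste0(paste(pieces, collapse = ""), bg(gap_len[n_gap]))
}

#' Specify one planted gene cluster
#'
#' @param gene_heme_counts Integer vector: planted motif count per gene.
#' @param exported_flags Logical vector, same length: whether each gene
#'   carries the signal-peptide cassette.
#' @param intergenic_bp Integer vector one shorter: nucleotide gap between
#'   consecutive genes (default 100 — comfortably inside the 500 bp join
#'   distance).
#' @param contig Contig name (default assigned at assembly time).
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(gene_heme_counts, exported_flags,
                         intergenic_bp = NULL, contig = NULL) {
  k <- length(gene_heme_counts)
  stopifnot(length(exported_flags) == k)
  if (is.null(intergenic_bp)) intergenic_bp <- rep(100L, max(k - 1L, 0L))
  stopifnot(length(intergenic_bp) == max(k - 1L, 0L))
  structure(
    list(gene_heme_counts = as.integer(gene_heme_counts),
         exported_flags = as.logical(exported_flags),
         intergenic_bp = as.integer(intergenic_bp),
         contig = contig),
    class = "cluster_spec"
  )
}

# independent restatement of the inclusion criteria for truth computation:
# chains split at gaps > max_intergenic_bp; a chain is a neighborhood iff it
# holds an exported gene with >= mhc_min hemes; it passes iff it also holds
# a >= heme_rich_min gene and >= min_total hemes in sum
cluster_truth <- function(spec, mhc_min = 3L, heme_rich_min = 4L,
                          min_total = 15L, max_intergenic_bp = 500L) {
  k <- length(spec$gene_heme_counts)
  breaks <- which(spec$intergenic_bp > max_intergenic_bp)
  chain_id <- cumsum(c(1L, as.integer(seq_len(k - 1L) %in% breaks)))
  out <- list()
  for (ch in unique(chain_id)) {
    idx <- which(chain_id == ch)
    hemes <- spec$gene_heme_counts[idx]
    exported <- spec$exported_flags[idx]
    has_seed <- any(exported & hemes >= mhc_min)
    if (!has_seed) next
    passes <- any(exported & hemes >= mhc_min) &&       # criterion 1
      any(hemes >= heme_rich_min) &&                    # criterion 2
      sum(hemes) >= min_total                           # criterion 3
    out[[length(out) + 1L]] <- tibble(
      member_index = list(idx),
      total_hemes = sum(hemes),
      expected_pass = passes
    )
  }
  bind_rows(out)
}

#' Generate a synthetic assembly with planted clusters and decoys
#'
#' Each cluster spec is laid out on its own contig with the requested
#' intergenic gaps; decoy genes (0–2 hemes, never exported) are placed on
#' the same contigs outside joining distance and on dedicated decoy
#' contigs. Nucleotide spans are synthesized as `3 * (protein_length + 1)`
#' bp on the `+` strand; no real codons are emitted (the pipeline is
#' protein-level). The truth table is computed by an independent
#' restatement of the three inclusion criteria, never by running the
#' pipeline.
#'
#' @param specs List of [cluster_spec()] objects (may be empty).
#' @param n_decoy_genes Number of decoy genes to add.
#' @param seed Integer seed; the whole assembly is a deterministic function
#'   of `(specs, n_decoy_genes, seed)`.
#' @param assembly_id Assembly label.
#' @return A list with `genes` (a gene table ready for [scan_genome()]) and
#'   `truth` (one row per expected neighborhood: `contig`, `gene_ids`
#'   list-column, `total_hemes`, `expected_pass`).
#' @export
simulate_assembly <- function(specs, n_decoy_genes = 10L, seed = 1L,
                              assembly_id = "synthetic") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  genes <- list()
  truth <- list()
  gene_n <- 0L
  add_gene <- function(contig, start, protein_seq) {
    gene_n <<- gene_n + 1L
    nt_len <- 3L * (nchar(protein_seq) + 1L)
    tibble(
      assembly_id = assembly_id,
      gene_id = sprintf("%s_%d", contig, gene_n),
      contig = contig,
      start = start, end = start + nt_len - 1L,
      strand = "+", protein_seq = protein_seq
    )
  }

  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    contig <- spec$contig %||% sprintf("ctg%03d", ci)
    pos <- 1L
    rows <- list()
    for (gi in seq_along(spec$gene_heme_counts)) {
      p <- make_protein(spec$gene_heme_counts[gi],
                        exported = spec$exported_flags[gi])
      g <- add_gene(contig, pos, p)
      rows[[gi]] <- g
      gap <- if (gi < length(spec$gene_heme_counts)) spec$intergenic_bp[gi] else 0L
      pos <- g$end + gap
    }
    rows <- bind_rows(rows)
    genes[[length(genes) + 1L]] <- rows
    tr <- cluster_truth(spec)
    if (nrow(tr) > 0L) {
      tr <- tr |>
        mutate(
          contig = contig,
          gene_ids = map(.data$member_index, ~ rows$gene_id[.x])
        ) |>
        select(all_of(c("contig", "gene_ids", "total_hemes",
                        "expected_pass")))
      truth[[length(truth) + 1L]] <- tr
    }
  }

  # decoys: half appended to cluster contigs beyond joining distance (they
  # must break the chain, not join it), half on dedicated contigs
  contig_end <- vapply(genes, function(g) max(g$end), integer(1))
  names(contig_end) <- vapply(genes, function(g) g$contig[1], character(1))
  if (n_decoy_genes > 0L) {
    for (di in seq_len(n_decoy_genes)) {
      p <- make_protein(sample(0:2, 1L), exported = FALSE)
      if (length(contig_end) > 0L && di %% 2L == 0L) {
        ci <- sample(seq_along(contig_end), 1L)
        contig <- names(contig_end)[ci]
        start <- contig_end[[ci]] + 600L + sample(0:400, 1L)
        g <- add_gene(contig, start, p)
        contig_end[[ci]] <- g$end
      } else {
        contig <- sprintf("decoy%03d", di)
        g <- add_gene(contig, 1L, p)
      }
      genes[[length(genes) + 1L]] <- g
    }
  }

  genes <- if (length(genes) > 0L) bind_rows(genes) else
    tibble(assembly_id = character(), gene_id = character(),
           contig = character(), start = integer(), end = integer(),
           strand = character(), protein_seq = character())
  truth <- if (length(truth) > 0L) bind_rows(truth) else
    tibble(contig = character(), gene_ids = list(),
           total_hemes = integer(), expected_pass = logical())
  genes <- finalize_gene_table(genes)
  list(genes = genes, truth = truth)
}

#' Write a synthetic assembly to disk as fixture files
#'
#' Emits `genome.faa` (protein FASTA with Prodigal-dialect headers),
#' `genome.gff` (GFF3 CDS rows) and `truth.tsv` into `dir`.
#'
#' @param sim Result of [simulate_assembly()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assembly_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sim$genes
  faa <- file.path(dir, "genome.faa")
  con <- file(faa, open = "wb")
  for (i in seq_len(nrow(genes))) {
    writeLines(sprintf(">%s # %d # %d # %s # ID=%d",
                       genes$gene_id[i], genes$start[i], genes$end[i],
                       if (genes$strand[i] == "+") "1" else "-1", i), con)
    writeLines(genes$protein_seq[i], con)
  }
  close(con)

  gff <- file.path(dir, "genome.gff")
  con <- file(gff, open = "wb")
  writeLines("##gff-version 3", con)
  writeLines(sprintf(
    "%s\themescan_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
    genes$contig, genes$start, genes$end, genes$strand, genes$gene_id
  ), con)
  close(con)

  truth <- sim$truth |>
    mutate(gene_ids = map_chr(.data$gene_ids, paste, collapse = ","))
  write_report_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
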