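# Reading and writing the standard formats the pipeline touches: protein
# FASTA (plain or Prodigal-dialect headers), GFF3 CDS rows, and the TSV
# reports. Everything is normalized into a "gene table": one row per CDS with
# contig, 1-based inclusive coordinates, strand, rank along the contig, and
# the protein sequence.

VALID_RESIDUES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "U"
)

#' Read a protein FASTA file
#'
#' Parses a protein multi-FASTA into a tibble with one row per record. The
#' gene identifier is the first whitespace-delimited token of the header;
#' sequences are uppercased and a single trailing stop character (`*`) is
#' stripped. Headers in the Prodigal dialect
#' (`id # start # end # strand # attrs`) are kept verbatim in the `header`
#' column so coordinates can be recovered with [parse_prodigal_header()].
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `gene_id`, `protein_seq`, `header`.
#' @seealso [assembly_from_prodigal()], [read_gff_cds()]
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 # 3 # 92 # 1 # ID=1_1", "MKC*"), faa)
#' read_protein_fasta(faa)
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(), protein_seq = character(),
                  header = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    abort(sprintf(
      "Malformed FASTA in '%s': sequence data at line 1 precedes any '>' header.",
      path
    ))
  }
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    function(x) paste(x, collapse = ""), character(1)
  )
  # records with no sequence lines still count (empty sequence)
  all_seqs <- setNames(rep("", length(headers)), as.character(seq_along(headers)))
  all_seqs[names(seqs)] <- seqs
  seqs <- toupper(unname(all_seqs))
  seqs <- sub("\\*$", "", seqs)

  bad <- grepl("\\*", seqs)
  if (any(bad)) {
    abort(sprintf(
      "Internal stop codon '*' in record(s): %s",
      paste(sub("\\s.*$", "", headers[bad]), collapse = ", ")
    ))
  }
  bad_res <- !grepl(sprintf("^[%s]*$", paste(VALID_RESIDUES, collapse = "")), seqs)
  if (any(bad_res)) {
    abort(sprintf(
      "Invalid residue characters in record(s): %s",
      paste(sub("\\s.*$", "", headers[bad_res]), collapse = ", ")
    ))
  }

  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate FASTA identifier(s): %s", paste(dup, collapse = ", ")))
  }
  tibble(gene_id = ids, protein_seq = seqs, header = headers)
}

#' Write a protein FASTA file
#'
#' Inverse of [read_protein_fasta()] on sequence content: records are written
#' in row order with the `gene_id` as the full header.
#'
#' @param proteins A data frame with columns `gene_id` and `protein_seq`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("gene_id", "protein_seq") %in% names(proteins)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$gene_id[i]), con)
    s <- proteins$protein_seq[i]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a Prodigal-dialect FASTA header
#'
#' Prodigal writes protein headers as `id # start # end # strand # attrs`
#' with strand coded 1 / -1 and 1-based inclusive nucleotide coordinates.
#'
#' @param header Header string (without the leading `>`).
#' @return A one-row tibble with `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), or `NULL` when the header is not in the Prodigal dialect
#'   (fewer than four `#`-separated fields), signalling the caller to fall
#'   back to a GFF annotation.
#' @examples
#' parse_prodigal_header("g1 # 3 # 92 # 1 # ID=1_1")
#' parse_prodigal_header("plain_header_no_hashes")
#' @export
parse_prodigal_header <- function(header) {
  parts <- str_trim(strsplit(header, "#", fixed = TRUE)[[1]])
  if (length(parts) < 4L) return(NULL)
  start <- suppressWarnings(as.integer(parts[2]))
  end <- suppressWarnings(as.integer(parts[3]))
  strand_raw <- parts[4]
  if (is.na(start) || is.na(end) || !strand_raw %in% c("1", "-1")) return(NULL)
  tibble(
    gene_id = sub("\\s.*$", "", parts[1]),
    start = start,
    end = end,
    strand = if (strand_raw == "1") "+" else "-"
  )
}

#' Build a gene table from Prodigal-dialect FASTA headers
#'
#' Recovers coordinates from Prodigal headers when no GFF is available. The
#' contig is taken as the gene identifier with its trailing `_<n>` gene
#' number removed (Prodigal names proteins `<contig>_<n>`).
#'
#' @param proteins Tibble from [read_protein_fasta()] (needs the `header`
#'   column).
#' @param assembly_id Label recorded in the `assembly_id` column.
#' @return A gene table: tibble with columns `assembly_id`, `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `rank`, `protein_seq`, sorted by
#'   contig then start, with `rank` the 0-based order along each contig.
#' @export
assembly_from_prodigal <- function(proteins, assembly_id = "assembly") {
  coords <- purrr::map(proteins$header, parse_prodigal_header)
  ok <- !vapply(coords, is.null, logical(1))
  if (!any(ok)) {
    abort("No Prodigal-dialect headers found; provide a GFF via read_gff_cds().")
  }
  if (!all(ok)) {
    warn(sprintf("%d record(s) without Prodigal coordinates were dropped.",
                 sum(!ok)))
  }
  genes <- bind_rows(coords[ok]) |>
    mutate(
      protein_seq = proteins$protein_seq[ok],
      contig = sub("_[0-9]+$", "", .data$gene_id),
      assembly_id = assembly_id
    )
  finalize_gene_table(genes)
}

#' Read CDS features from a GFF3 file and join them to proteins
#'
#' Only rows of type `CDS` are used. Identifier matching between the GFF and
#' the FASTA tries, in order, the `ID`, `locus_tag`, and `protein_id`
#' attributes; the first scheme with at least one match is used for the whole
#' file (schemes are never mixed). Proteins without a matching CDS produce a
#' warning; CDS rows without a matching protein are skipped silently. When
#' both Prodigal headers and a GFF are supplied the GFF wins: the explicit
#' annotation is authoritative.
#'
#' @param path Path to a GFF3 file.
#' @param proteins Tibble from [read_protein_fasta()].
#' @param assembly_id Label recorded in the `assembly_id` column.
#' @return A gene table (see [assembly_from_prodigal()] for columns).
#' @export
read_gff_cds <- function(path, proteins, assembly_id = "assembly") {
  gff <- as_tibble(rtracklayer::readGFF(path))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) abort(sprintf("No CDS features in '%s'.", path))

  schemes <- c("ID", "locus_tag", "protein_id")
  matched <- NULL
  for (sc in schemes) {
    if (!sc %in% names(cds)) next
    key <- as.character(cds[[sc]])
    hit <- !is.na(key) & key %in% proteins$gene_id
    if (any(hit)) {
      matched <- tibble(
        gene_id = key[hit],
        contig = as.character(cds$seqid[hit]),
        start = as.integer(cds$start[hit]),
        end = as.integer(cds$end[hit]),
        strand = as.character(cds$strand[hit])
      )
      break
    }
  }
  if (is.null(matched)) {
    abort(sprintf(
      "No CDS identifiers in '%s' (tried %s) match the FASTA gene ids; check the annotation's ID scheme.",
      path, paste(schemes, collapse = ", ")
    ))
  }
  matched <- distinct(matched, .data$gene_id, .keep_all = TRUE)
  missing <- setdiff(proteins$gene_id, matched$gene_id)
  if (length(missing) > 0L) {
    warn(sprintf("%d protein(s) have no matching CDS row (e.g. %s).",
                 length(missing), head(missing, 3)[1]))
  }
  genes <- matched |>
    left_join(proteins[, c("gene_id", "protein_seq")], by = "gene_id") |>
    mutate(assembly_id = assembly_id)
  finalize_gene_table(genes)
}

# sort within contig by (start, end) and assign 0-based ranks
finalize_gene_table <- function(genes) {
  stopifnot(all(genes$start >= 1L), all(genes$end >= genes$start),
            all(genes$strand %in% c("+", "-")))
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate gene id(s) in assembly: %s",
                  paste(dup, collapse = ", ")))
  }
  genes |>
    arrange(.data$contig, .data$start, .data$end) |>
    group_by(.data$contig) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select(all_of(c("assembly_id", "gene_id", "contig", "start", "end",
                    "strand", "rank", "protein_seq")))
}

# deterministic TSV writer: '#'-prefixed header, fixed column order, "\n" EOL
write_report_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L) {
    body <- do.call(paste, c(lapply(df, format_tsv_col), list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.logical(x)) return(ifelse(x, "True", "False"))
  if (is.double(x)) return(formatC(x, digits = 6, format = "g"))
  as.character(x)
}

#' Write the neighborhoods report
#'
#' One row per gene neighborhood, ordered by assembly, contig, then first-gene
#' start; byte-identical output for identical input.
#'
#' @param neighborhoods Tibble from [apply_criteria()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_tsv <- function(neighborhoods, path) {
  cols <- c("assembly_id", "neighborhood_id", "contig", "first_gene_start",
            "last_gene_end", "n_genes", "n_mhc", "n_heme_rich", "total_hemes",
            "has_sp_mhc", "passes", "criteria_failed", "gene_ids")
  df <- neighborhoods |>
    mutate(
      gene_ids = map_chr(.data$members, ~ paste(.x$gene_id, collapse = ",")),
      criteria_failed = map_chr(.data$criteria_failed,
                                ~ paste(.x, collapse = ","))
    ) |>
    arrange(.data$assembly_id, .data$contig, .data$first_gene_start) |>
    select(all_of(cols))
  write_report_tsv(df, path)
}

#' Write the per-protein report
#'
#' One row per protein with heme counts, classification flags and the
#' localization call, ordered by assembly, contig, then start coordinate.
#'
#' @param proteins Per-protein tibble (e.g. the `proteins` element of
#'   [scan_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_tsv <- function(proteins, path) {
  cols <- c("assembly_id", "gene_id", "contig", "start", "end", "strand",
            "length", "heme_count", "is_mhc", "is_heme_rich", "is_high_heme",
            "has_signal_peptide", "n_tm", "localization", "source")
  df <- proteins |>
    mutate(length = nchar(.data$protein_seq)) |>
    arrange(.data$assembly_id, .data$contig, .data$start) |>
    select(all_of(cols))
  write_report_tsv(df, path)
}

#' Write the pilin candidates report
#'
#' @param pilins Tibble from [detect_t4ap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pilin_tsv <- function(pilins, path) {
  cols <- c("assembly_id", "gene_id", "length", "length_ok", "motif_ok",
            "mature_start", "aromatic_fraction", "is_candidate")
  df <- pilins |>
    arrange(.data$assembly_id, .data$gene_id) |>
    select(all_of(cols))
  write_report_tsv(df, path)
}

#' Write the protein-families report
#'
#' @param families Tibble from [filter_families()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_families_tsv <- function(families, path) {
  cols <- c("family_id", "size", "centroid_id", "hmm_eligible", "mean_hemes")
  df <- families |>
    mutate(size = map_int(.data$member_ids, length)) |>
    arrange(.data$family_id) |>
    select(all_of(cols))
  write_report_tsv(df, path)
}
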