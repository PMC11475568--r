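# Protein-family construction for HMM development: greedy centroid
# clustering of the discovered MHCs, a center-star progressive alignment of
# each family against its centroid, masking of mostly-gap columns, and
# export of builder-ready Stockholm / aligned-FASTA files. Pairwise global
# alignment is delegated to Biostrings (Needleman-Wunsch, BLOSUM62, affine
# gaps); the clustering, column merge, masking and export logic is native.

#' Family clustering configuration
#'
#' @param identity_threshold Minimum global identity (matches over alignment
#'   columns, terminal gaps excluded) between a member and its centroid
#'   (default 0.5).
#' @param coverage_threshold Minimum fraction of the shorter sequence
#'   covered by aligned (residue-to-residue) columns (default 0.8).
#' @param gap_mask_fraction Columns whose gap fraction strictly exceeds
#'   this are removed by [mask_alignment()] (default 0.5 — the literal
#'   reading of "mostly gaps").
#' @param min_family_size Minimum member count for a family to be eligible
#'   for HMM building (default 3 orthologs).
#' @return A list of class `family_config`.
#' @export
family_config <- function(identity_threshold = 0.5, coverage_threshold = 0.8,
                          gap_mask_fraction = 0.5, min_family_size = 3L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1,
            gap_mask_fraction > 0, gap_mask_fraction <= 1,
            min_family_size >= 1L)
  structure(
    list(identity_threshold = identity_threshold,
         coverage_threshold = coverage_threshold,
         gap_mask_fraction = gap_mask_fraction,
         min_family_size = as.integer(min_family_size)),
    class = "family_config"
  )
}

# global (Needleman-Wunsch) alignment of two sequences; returns the aligned
# rows plus identity (matches / columns excluding terminal gaps) and
# coverage (both-residue columns / length of the shorter sequence)
align_pair <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  row_a <- as.character(Biostrings::alignedPattern(pa))
  row_b <- as.character(Biostrings::alignedSubject(pa))
  stats <- alignment_stats(row_a, row_b)
  list(row_a = row_a, row_b = row_b, score = Biostrings::score(pa),
       identity = stats$identity, coverage = stats$coverage)
}

alignment_stats <- function(row_a, row_b) {
  ca <- strsplit(row_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(row_b, "", fixed = TRUE)[[1]]
  gap_a <- ca == "-"; gap_b <- cb == "-"
  non_term <- rep(TRUE, length(ca))
  # terminal gap columns: leading/trailing run of gaps in either row
  run_head <- cumprod(gap_a | gap_b) == 1
  run_tail <- rev(cumprod(rev(gap_a | gap_b)) == 1)
  core <- !(run_head | run_tail)
  n_cols <- sum(core)
  matches <- sum(core & ca == cb & !gap_a)
  both <- sum(!gap_a & !gap_b)
  shorter <- min(sum(!gap_a), sum(!gap_b))
  list(
    identity = if (n_cols > 0) matches / n_cols else 0,
    coverage = if (shorter > 0) both / shorter else 0
  )
}

#' Greedily cluster sequences into centroid families
#'
#' Sequences are processed in order of decreasing length (ties broken by
#' identifier for determinism). Each sequence joins the first existing
#' centroid (in creation order) whose global identity reaches
#' `identity_threshold` with coverage at least `coverage_threshold` of the
#' shorter sequence; otherwise it founds a new family as its centroid.
#'
#' @param sequences A data frame with columns `gene_id` and `protein_seq`.
#' @param config A [family_config()].
#' @return A tibble with one row per family: `family_id`, `centroid_id`,
#'   `member_ids` (list-column, centroid first), `size`.
#' @export
greedy_cluster <- function(sequences, config = family_config()) {
  stopifnot(all(c("gene_id", "protein_seq") %in% names(sequences)))
  if (nrow(sequences) == 0L) {
    return(tibble(family_id = character(), centroid_id = character(),
                  member_ids = list(), size = integer()))
  }
  ord <- order(-nchar(sequences$protein_seq), sequences$gene_id)
  ids <- sequences$gene_id[ord]
  seqs <- sequences$protein_seq[ord]

  centroid_ids <- character(0)
  centroid_seqs <- character(0)
  members <- list()
  for (i in seq_along(ids)) {
    assigned <- NA_integer_
    for (k in seq_along(centroid_ids)) {
      al <- align_pair(centroid_seqs[k], seqs[i])
      if (al$identity >= config$identity_threshold &&
          al$coverage >= config$coverage_threshold) {
        assigned <- k
        break
      }
    }
    if (is.na(assigned)) {
      centroid_ids <- c(centroid_ids, ids[i])
      centroid_seqs <- c(centroid_seqs, seqs[i])
      members[[length(members) + 1L]] <- ids[i]
    } else {
      members[[assigned]] <- c(members[[assigned]], ids[i])
    }
  }
  tibble(
    family_id = sprintf("fam_%03d", seq_along(centroid_ids)),
    centroid_id = centroid_ids,
    member_ids = members,
    size = vapply(members, length, integer(1))
  )
}

#' Align one family by center-star against its centroid
#'
#' Every member is globally aligned to the centroid; the pairwise alignments
#' are merged on centroid columns, taking for each centroid position the
#' maximum insertion length observed among members. This is the classic
#' center-star construction — adequate for the closely related members a
#' >= 50% identity family contains.
#'
#' @param sequences A data frame with `gene_id` and `protein_seq` covering
#'   all members.
#' @param centroid_id,member_ids Centroid and member identifiers (centroid
#'   may appear in `member_ids`; it anchors the alignment either way).
#' @return A named character vector of aligned rows (equal length, `-`
#'   gaps), centroid first, other members in `member_ids` order.
#' @export
align_family <- function(sequences, centroid_id, member_ids) {
  seq_of <- setNames(sequences$protein_seq, sequences$gene_id)
  if (!centroid_id %in% names(seq_of)) {
    abort(sprintf("Centroid '%s' not found in sequences.", centroid_id))
  }
  others <- setdiff(member_ids, centroid_id)
  cen <- seq_of[[centroid_id]]
  if (length(others) == 0L) return(setNames(cen, centroid_id))

  pair_rows <- lapply(others, function(id) align_pair(cen, seq_of[[id]]))

  # per pairwise alignment, split the member row into blocks keyed by the
  # centroid position each block follows (0 = before the first residue)
  cen_len <- nchar(cen)
  blocks <- lapply(pair_rows, function(al) {
    ca <- strsplit(al$row_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(al$row_b, "", fixed = TRUE)[[1]]
    pos <- cumsum(ca != "-")         # centroid position per column
    split(cb, pos)                   # insertions group with the preceding residue
  })
  # maximum insertion length after each centroid position across members
  ins_len <- integer(cen_len + 1L)   # index 1 = "after position 0"
  for (b in blocks) {
    for (nm in names(b)) {
      p <- as.integer(nm)
      extra <- length(b[[nm]]) - (if (p == 0L) 0L else 1L)
      ins_len[p + 1L] <- max(ins_len[p + 1L], extra)
    }
  }
  pad <- function(chars, width) c(chars, rep("-", width - length(chars)))
  build_row <- function(b) {
    out <- character(0)
    for (p in 0:cen_len) {
      blk <- b[[as.character(p)]]
      if (p == 0L) {
        out <- c(out, pad(blk %||% character(0), ins_len[1L]))
      } else {
        blk <- blk %||% "-"
        out <- c(out, blk[1L], pad(blk[-1L], ins_len[p + 1L]))
      }
    }
    paste(out, collapse = "")
  }
  cen_row <- {
    b <- split(strsplit(cen, "", fixed = TRUE)[[1]],
               seq_len(cen_len))
    build_row(b)
  }
  rows <- vapply(blocks, build_row, character(1))
  setNames(c(cen_row, rows), c(centroid_id, others))
}

#' Remove mostly-gap columns from an alignment
#'
#' A column is removed iff its gap fraction strictly exceeds
#' `gap_mask_fraction`; a column exactly at the threshold is retained. Row
#' order is preserved; masking is idempotent.
#'
#' @param msa Character vector of equal-length aligned rows (`-` gaps).
#' @param gap_mask_fraction Gap-fraction cutoff (default 0.5).
#' @return The masked alignment (same names, possibly fewer columns).
#' @export
mask_alignment <- function(msa, gap_mask_fraction = 0.5) {
  if (length(msa) == 0L) return(msa)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) {
    abort("Ragged alignment: rows have unequal lengths.")
  }
  if (widths[1] == 0L) return(msa)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= gap_mask_fraction
  setNames(apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""),
           names(msa))
}

#' Set HMM eligibility flags on families
#'
#' A family is eligible for profile-HMM building when it holds at least
#' `min_family_size` members (orthologs).
#'
#' @param families Tibble from [greedy_cluster()].
#' @param min_family_size Minimum member count (default 3).
#' @return `families` with an `hmm_eligible` column.
#' @export
filter_families <- function(families, min_family_size = 3L) {
  mutate(families,
         hmm_eligible = map_int(.data$member_ids, length) >= min_family_size)
}

#' Export masked alignments for eligible families
#'
#' Writes one Stockholm 1.0 file (`family_<id>.sto`) and one aligned FASTA
#' (`family_<id>.afa`) per HMM-eligible family, deterministically named and
#' byte-stable across reruns; these are ready for an external `hmmbuild`.
#'
#' @param families Tibble from [filter_families()].
#' @param sequences A data frame with `gene_id` and `protein_seq` covering
#'   all members.
#' @param dir Output directory (created if needed).
#' @param config A [family_config()] (controls the gap mask).
#' @return A tibble of written files (`family_id`, `stockholm`, `fasta`);
#'   zero rows (with a message) when no family is eligible.
#' @export
export_family_alignments <- function(families, sequences, dir,
                                     config = family_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eligible <- families[families$hmm_eligible, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    inform("No HMM-eligible families; nothing exported.")
    return(tibble(family_id = character(), stockholm = character(),
                  fasta = character()))
  }
  out <- pmap(
    list(eligible$family_id, eligible$centroid_id, eligible$member_ids),
    function(fid, cen, mem) {
      msa <- align_family(sequences, cen, mem)
      masked <- mask_alignment(msa, config$gap_mask_fraction)
      sto <- file.path(dir, paste0("family_", fid, ".sto"))
      afa <- file.path(dir, paste0("family_", fid, ".afa"))
      write_stockholm(masked, sto)
      write_protein_fasta(
        tibble(gene_id = names(masked), protein_seq = unname(masked)),
        afa
      )
      tibble(family_id = fid, stockholm = sto, fasta = afa)
    }
  )
  bind_rows(out)
}

write_stockholm <- function(msa, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  name_w <- max(nchar(names(msa)))
  writeLines(sprintf(paste0("%-", name_w, "s  %s"), names(msa), unname(msa)),
             con)
  writeLines("//", con)
  invisible(path)
}
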