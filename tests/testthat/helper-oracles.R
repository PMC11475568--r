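# Independent oracles for property tests. These deliberately do not share
# code with the package: the motif oracle enumerates every (start, template)
# match before selecting greedily; the segment oracle tests each window on
# its own and merges covered indices; the alignment oracle is a from-scratch
# Gotoh affine-gap DP.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# all-start-positions motif oracle with greedy left-to-right non-overlap
oracle_scan_hemes <- function(seq, patterns = c("CxxCH", "CxxxCH",
                                                "CxxxxCH", "CxxCK")) {
  n <- nchar(seq)
  # enumerate every match of every template at every start (overlapping
  # occurrences included, via zero-width lookahead)
  all_hits <- list()
  for (ti in seq_along(patterns)) {
    p <- patterns[ti]
    len <- nchar(p)
    regex <- gsub("x", ".", p, fixed = TRUE)
    if (n < len) next
    m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    for (s in starts) {
      all_hits[[length(all_hits) + 1L]] <-
        list(start = s, end = s + len - 1L, len = len, order = ti,
             text = substr(seq, s, s + len - 1L), template = p)
    }
  }
  if (length(all_hits) == 0L) {
    return(data.frame(start_pos = integer(0), matched_text = character(0),
                      template = character(0)))
  }
  # greedy selection: smallest start, then shortest template, then config order
  starts <- vapply(all_hits, `[[`, numeric(1), "start")
  lens <- vapply(all_hits, `[[`, numeric(1), "len")
  orders <- vapply(all_hits, `[[`, numeric(1), "order")
  idx <- order(starts, lens, orders)
  all_hits <- all_hits[idx]
  chosen <- list()
  blocked_until <- 0L
  for (h in all_hits) {
    if (h$start > blocked_until) {
      chosen[[length(chosen) + 1L]] <- h
      blocked_until <- h$end
    }
  }
  data.frame(
    start_pos = vapply(chosen, function(h) as.integer(h$start), integer(1)),
    matched_text = vapply(chosen, `[[`, character(1), "text"),
    template = vapply(chosen, `[[`, character(1), "template"),
    stringsAsFactors = FALSE
  )
}

# per-window hydrophobic segment oracle: mark indices covered by any
# qualifying window, return maximal runs
oracle_hydrophobic_segments <- function(seq, window = 19L, min_mean = 1.6) {
  kd <- hemescan::kyte_doolittle
  n <- nchar(seq)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  h <- as.integer(round(10 * unname(kd[strsplit(seq, "")[[1]]])))
  covered <- logical(n)
  for (i in 1:(n - window + 1L)) {
    if (sum(h[i:(i + window - 1L)]) >= 10 * min_mean * window) {
      covered[i:(i + window - 1L)] <- TRUE
    }
  }
  if (!any(covered)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Gotoh global alignment with affine gaps (cost open + k*extend), BLOSUM62;
# returns optimal score and, via traceback, an identity computed the same
# way as the package (matches / non-terminal-gap columns)
oracle_global_align <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # av[i] aligned to bv[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + extend * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                     Y[i - 1, j] - open - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                     X[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# literal restatement of the three inclusion criteria on raw per-gene facts
oracle_criteria_pass <- function(heme_counts, exported, mhc_min = 3L,
                                 heme_rich_min = 4L, min_total = 15L) {
  any(exported & heme_counts >= mhc_min) &&
    any(heme_counts >= heme_rich_min) &&
    sum(heme_counts) >= min_total
}

# localization-call stub for neighborhood tests that fabricate evidence
fake_localization <- function(gene_id, localization) {
  tibble::tibble(
    gene_id = gene_id,
    has_signal_peptide = localization == "exported",
    sp_start = NA_integer_, sp_end = NA_integer_,
    n_tm = ifelse(localization == "inner_membrane", 1L, 0L),
    tm_helices = replicate(length(gene_id),
                           tibble::tibble(start = integer(0),
                                          end = integer(0)),
                           simplify = FALSE),
    localization = localization,
    source = "builtin"
  )
}

# heme-annotation stub keyed by desired counts
fake_annotation <- function(gene_id, heme_count, config = hemescan::heme_config()) {
  hemescan::classify_hemes(
    tibble::tibble(gene_id = gene_id, heme_count = as.integer(heme_count)),
    config
  )
}

# minimal gene-table builder for rule-level neighborhood tests
fake_genes <- function(contig, starts, ends, assembly_id = "asm") {
  tibble::tibble(
    assembly_id = assembly_id,
    gene_id = sprintf("%s_g%d", contig, seq_along(starts)),
    contig = contig,
    start = as.integer(starts), end = as.integer(ends),
    strand = "+",
    rank = seq_along(starts) - 1L,
    protein_seq = strrep("A", 10)
  )
}
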