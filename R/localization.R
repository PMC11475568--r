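# Per-protein localization: exported (periplasmic / outer-membrane /
# secreted candidate), inner-membrane, or cytoplasmic. The built-in rule is
# a transparent Kyte-Doolittle hydropathy heuristic; external Phobius
# predictions can be parsed and merged in as a pluggable upgrade.

#' Kyte-Doolittle hydropathy scale
#'
#' The 20 standard residue hydropathy values; ambiguous residues `X` and `U`
#' map to 0.
#' @format Named numeric vector.
#' @export
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0, U = 0
)

#' Localization heuristic parameters
#'
#' @param window Sliding-window width in residues for mean hydropathy
#'   (default 19, the classic transmembrane-scan width).
#' @param hydropathy_min Mean Kyte-Doolittle hydropathy a window must reach
#'   to count as hydrophobic (default 1.6).
#' @param sp_max_start Latest residue index at which a signal-peptide
#'   hydrophobic segment may begin (default 10).
#' @param sp_max_end Latest residue index at which it may end (default 45).
#' @param charge_window N-terminal span (residues) that must contain at
#'   least one Lys/Arg — the positively charged n-region of a signal
#'   peptide (default 10).
#' @return A list of class `localization_params`.
#' @export
localization_params <- function(window = 19L, hydropathy_min = 1.6,
                                sp_max_start = 10L, sp_max_end = 45L,
                                charge_window = 10L) {
  structure(
    list(window = as.integer(window), hydropathy_min = hydropathy_min,
         sp_max_start = as.integer(sp_max_start),
         sp_max_end = as.integer(sp_max_end),
         charge_window = as.integer(charge_window)),
    class = "localization_params"
  )
}

# maximal hydrophobic segments: union of all windows whose mean hydropathy
# reaches the threshold, overlapping windows merged into intervals
hydrophobic_segments <- function(protein_seq, params) {
  n <- nchar(protein_seq)
  w <- params$window
  if (n < w) return(tibble(start = integer(0), end = integer(0)))
  # the scale has one decimal place: integer deci-units keep window sums
  # exact, so the threshold comparison is free of floating-point drift
  h10 <- as.integer(round(10 * unname(
    kyte_doolittle[strsplit(protein_seq, "", fixed = TRUE)[[1]]]
  )))
  csum <- c(0L, cumsum(h10))
  sums <- csum[(w + 1L):(n + 1L)] - csum[1L:(n - w + 1L)]
  ok <- which(sums >= 10 * params$hydropathy_min * w)
  if (length(ok) == 0L) return(tibble(start = integer(0), end = integer(0)))
  # merge window intervals [i, i+w-1] that overlap
  brk <- which(diff(ok) > w)
  seg_start <- ok[c(1L, brk + 1L)]
  seg_end <- ok[c(brk, length(ok))] + w - 1L
  tibble(start = seg_start, end = seg_end)
}

#' Predict protein localization with the built-in hydropathy heuristic
#'
#' Deterministic rule per protein: (1) find maximal hydrophobic segments as
#' merged runs of 19-residue windows with mean Kyte-Doolittle hydropathy
#' >= 1.6; (2) a segment starting at residue <= 10, ending at residue <= 45,
#' with at least one Lys/Arg in the N-terminal charge window is called the
#' signal peptide (its span plus 3 residues, capped at the sequence length);
#' (3) every other hydrophobic segment is a transmembrane helix; (4) the
#' protein is `exported` if it has a signal peptide and no TM helix,
#' `inner_membrane` if it has any TM helix (membrane-anchored even when a
#' signal peptide is also present), else `cytoplasmic`.
#'
#' @param genes A data frame with columns `gene_id` and `protein_seq`.
#' @param params A [localization_params()].
#' @return A tibble with one row per gene: `gene_id`, `has_signal_peptide`,
#'   `sp_start`, `sp_end`, `n_tm`, `tm_helices` (list-column of span
#'   tibbles), `localization`, `source` (`"builtin"`).
#' @export
predict_localization <- function(genes, params = localization_params()) {
  stopifnot(all(c("gene_id", "protein_seq") %in% names(genes)))
  if (nrow(genes) == 0L) return(empty_localization())
  calls <- map2(genes$gene_id, genes$protein_seq, function(id, seq) {
    localize_one(id, seq, params)
  })
  bind_rows(calls)
}

empty_localization <- function() {
  tibble(
    gene_id = character(), has_signal_peptide = logical(),
    sp_start = integer(), sp_end = integer(), n_tm = integer(),
    tm_helices = list(), localization = character(), source = character()
  )
}

localize_one <- function(gene_id, protein_seq, params) {
  n <- nchar(protein_seq)
  segs <- hydrophobic_segments(protein_seq, params)
  nterm <- substr(protein_seq, 1L, min(params$charge_window, n))
  has_charge <- grepl("[KR]", nterm)
  sp_idx <- which(segs$start <= params$sp_max_start &
                    segs$end <= params$sp_max_end & has_charge)
  has_sp <- length(sp_idx) > 0L
  sp_start <- NA_integer_; sp_end <- NA_integer_
  tm <- segs
  if (has_sp) {
    sp_idx <- sp_idx[1L]
    sp_start <- 1L
    sp_end <- min(segs$end[sp_idx] + 3L, n)
    tm <- segs[-sp_idx, , drop = FALSE]
  }
  loc <- if (nrow(tm) > 0L) "inner_membrane"
         else if (has_sp) "exported"
         else "cytoplasmic"
  tibble(
    gene_id = gene_id,
    has_signal_peptide = has_sp,
    sp_start = sp_start, sp_end = sp_end,
    n_tm = nrow(tm),
    tm_helices = list(tm),
    localization = loc,
    source = "builtin"
  )
}

#' Parse a Phobius short-format results table
#'
#' The Phobius "short" output is whitespace-delimited with one row per
#' sequence: `SEQENCE_ID  TM  SP  PREDICTION` where `TM` is the predicted
#' transmembrane-helix count, `SP` is `Y` or `0`, and `PREDICTION` is the
#' topology string. Localization follows the same final rule as the built-in
#' heuristic: exported needs `SP == Y` and zero TM helices; any TM helix
#' means inner membrane.
#'
#' @param path Path to a Phobius short-format file (a header line starting
#'   with `SEQENCE` is skipped).
#' @return A tibble shaped like [predict_localization()] output with
#'   `source = "external"`. Unparseable rows are skipped with a warning;
#'   zero parsed rows is an error.
#' @export
parse_phobius_short <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^SEQ", lines, ignore.case = TRUE)]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(str_trim(ln), "\\s+")[[1]]
    tm <- suppressWarnings(as.integer(f[2]))
    if (length(f) < 3L || is.na(tm) || !f[3] %in% c("Y", "0")) {
      warn(sprintf("Skipping unparseable Phobius row: '%s'", ln))
      next
    }
    has_sp <- f[3] == "Y"
    loc <- if (tm > 0L) "inner_membrane" else if (has_sp) "exported" else "cytoplasmic"
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = f[1], has_signal_peptide = has_sp,
      sp_start = NA_integer_, sp_end = NA_integer_,
      n_tm = tm, tm_helices = list(tibble(start = integer(0), end = integer(0))),
      localization = loc, source = "external"
    )
  }
  if (length(rows) == 0L) {
    abort(sprintf("No parseable rows in Phobius file '%s'.", path))
  }
  bind_rows(rows)
}

#' Merge built-in and external localization calls
#'
#' Under the default `external_wins` policy the external call is used
#' wherever available and the built-in heuristic fills the gaps; provenance
#' stays in the `source` column. Genes listed in `gene_ids` but absent from
#' both sources are conservatively called cytoplasmic with a warning.
#'
#' @param builtin Tibble from [predict_localization()] (may be `NULL`).
#' @param external Tibble from [parse_phobius_short()] (may be `NULL`).
#' @param gene_ids Optional character vector of all genes that must receive
#'   a call.
#' @param policy Merge policy; only `"external_wins"` is defined.
#' @return One localization call per gene.
#' @export
merge_localization <- function(builtin, external = NULL, gene_ids = NULL,
                               policy = "external_wins") {
  stopifnot(identical(policy, "external_wins"))
  merged <- if (is.null(external)) builtin
    else if (is.null(builtin)) external
    else bind_rows(external, builtin[!builtin$gene_id %in% external$gene_id, ])
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, merged$gene_id)
    if (length(missing) > 0L) {
      warn(sprintf(
        "%d gene(s) without a localization call treated as cytoplasmic (e.g. %s).",
        length(missing), missing[1]
      ))
      filler <- tibble(
        gene_id = missing, has_signal_peptide = FALSE,
        sp_start = NA_integer_, sp_end = NA_integer_, n_tm = 0L,
        tm_helices = rep(list(tibble(start = integer(0), end = integer(0))),
                         length(missing)),
        localization = "cytoplasmic", source = "default"
      )
      merged <- bind_rows(merged, filler)
    }
    merged <- merged[match(gene_ids, merged$gene_id), , drop = FALSE]
  }
  merged
}
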