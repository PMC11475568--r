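test_that("protein FASTA parsing strips stops, uppercases, and keeps Prodigal headers", {
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1", "MKC*"), faa)
  p <- read_protein_fasta(faa)
  expect_equal(p$gene_id, "g1")
  expect_equal(p$protein_seq, "MKC")

  writeLines(c(">g1 # 3 # 92 # 1 # ID=1_1", "mk"), faa)
  p <- read_protein_fasta(faa)
  expect_equal(p$protein_seq, "MK")
  coords <- parse_prodigal_header(p$header)
  expect_equal(coords$start, 3L)
  expect_equal(coords$end, 92L)
  expect_equal(coords$strand, "+")

  # multi-line sequences concatenate
  writeLines(c(">a", "MK", "CC", ">b", "GG"), faa)
  p <- read_protein_fasta(faa)
  expect_equal(p$protein_seq, c("MKCC", "GG"))
})

test_that("malformed FASTA and duplicate identifiers are rejected by name", {
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c("MKC", ">g1", "MK"), faa)
  expect_error(read_protein_fasta(faa), "line 1")

  writeLines(c(">g1", "MK", ">g1", "CC"), faa)
  expect_error(read_protein_fasta(faa), "g1")
})

test_that("Prodigal header grammar parses both strands and rejects non-Prodigal headers", {
  h <- parse_prodigal_header("g1 # 3 # 92 # 1 # ID=1_1")
  expect_equal(unlist(h[1, c("gene_id", "strand")]),
               c(gene_id = "g1", strand = "+"))
  h <- parse_prodigal_header("g2 # 100 # 300 # -1 # x")
  expect_equal(h$strand, "-")
  expect_equal(c(h$start, h$end), c(100L, 300L))
  expect_null(parse_prodigal_header("plain_header_no_hashes"))
})

test_that("FASTA write/read round-trips sequence content", {
  set.seed(11)
  prot <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8),
    protein_seq = vapply(sample(5:150, 8), random_protein, character(1))
  )
  faa <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(prot, faa)
  back <- read_protein_fasta(faa)
  expect_equal(back$gene_id, prot$gene_id)
  expect_equal(back$protein_seq, prot$protein_seq)
})

test_that("GFF CDS rows join to proteins and ranks follow start coordinates", {
  faa_tbl <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    protein_seq = c("MKA", "MKG", "MKT"),
    header = c("gA", "gB", "gC")
  )
  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tCDS\t900\t980\t.\t+\t0\tID=gC",
    "c1\tsrc\tCDS\t10\t90\t.\t+\t0\tID=gA",
    "c1\tsrc\tCDS\t200\t400\t.\t-\t0\tID=gB"
  ), gff)
  asm <- read_gff_cds(gff, faa_tbl, assembly_id = "t")
  expect_equal(asm$gene_id, c("gA", "gB", "gC"))
  expect_equal(asm$rank, c(0L, 1L, 2L))
  expect_equal(asm$strand, c("+", "-", "+"))
  expect_equal(sum(!is.na(asm$protein_seq)), 3L)
})

test_that("GFF identifier matching falls back to locus_tag and errors on zero matches", {
  faa_tbl <- tibble::tibble(gene_id = c("lt1", "lt2"),
                            protein_seq = c("MK", "MG"), header = c("lt1", "lt2"))
  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tCDS\t1\t30\t.\t+\t0\tID=cds1;locus_tag=lt1",
    "c1\tsrc\tCDS\t50\t80\t.\t+\t0\tID=cds2;locus_tag=lt2"
  ), gff)
  asm <- read_gff_cds(gff, faa_tbl)
  expect_setequal(asm$gene_id, c("lt1", "lt2"))

  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tCDS\t1\t30\t.\t+\t0\tID=nomatch"
  ), gff)
  expect_error(read_gff_cds(gff, faa_tbl), "ID scheme|match", ignore.case = TRUE)
})

test_that("assembly built from Prodigal headers sorts and ranks per contig", {
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(
    ">c1_2 # 500 # 700 # -1 # ID=2", "MKGG",
    ">c1_1 # 10 # 90 # 1 # ID=1", "MKAA",
    ">c2_1 # 5 # 40 # 1 # ID=3", "MKTT"
  ), faa)
  asm <- assembly_from_prodigal(read_protein_fasta(faa), "t")
  expect_equal(nrow(asm), 3L)
  c1 <- asm[asm$contig == "c1", ]
  expect_equal(c1$gene_id, c("c1_1", "c1_2"))
  expect_equal(c1$rank, c(0L, 1L))
  expect_equal(asm$rank[asm$contig == "c2"], 0L)
})

test_that("report TSVs are byte-deterministic and header-only when empty", {
  sim <- simulate_assembly(list(cluster_spec(c(5, 10), c(TRUE, FALSE))),
                           n_decoy_genes = 3, seed = 3)
  res <- scan_genome(sim$genes)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_neighborhood_tsv(res$neighborhoods, f1)
  write_neighborhood_tsv(res$neighborhoods, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  write_neighborhood_tsv(res$neighborhoods[0, ], f1)
  lines <- readLines(f1)
  expect_length(lines, 1L)
  expect_match(lines, "^#assembly_id\t")

  # one neighborhood of 2 genes -> 1 report row
  sim2 <- simulate_assembly(list(cluster_spec(c(10, 10), c(TRUE, TRUE))),
                            n_decoy_genes = 0, seed = 4)
  res2 <- scan_genome(sim2$genes)
  write_neighborhood_tsv(res2$neighborhoods, f1)
  expect_length(readLines(f1), 2L)
  expect_equal(res2$neighborhoods$n_genes, 2L)
})
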