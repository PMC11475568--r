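test_that("seed-and-extend chains genes within 500 bp and stops at larger gaps", {
  g <- fake_genes("c1", starts = c(1, 350, 2000), ends = c(300, 900, 2500))
  ann <- fake_annotation(g$gene_id, c(0, 5, 0))
  loc <- fake_localization(g$gene_id,
                           c("cytoplasmic", "exported", "cytoplasmic"))
  nb <- build_neighborhoods(g, ann, loc)
  expect_equal(nrow(nb), 1L)
  expect_setequal(nb$members[[1]]$gene_id, g$gene_id[1:2])  # gap 50 joins, 1100 breaks
})

test_that("single-gene contigs and seedless contigs behave per the rule", {
  g <- fake_genes("c1", 1, 400)
  nb <- build_neighborhoods(g, fake_annotation(g$gene_id, 4),
                            fake_localization(g$gene_id, "exported"))
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$n_genes, 1L)

  g2 <- fake_genes("c2", c(1, 400), c(300, 900))
  nb2 <- build_neighborhoods(g2, fake_annotation(g2$gene_id, c(10, 10)),
                             fake_localization(g2$gene_id,
                                               c("cytoplasmic", "inner_membrane")))
  expect_equal(nrow(nb2), 0L)
})

test_that("a missing annotation is a hard error naming the gene", {
  g <- fake_genes("c1", 1, 300)
  ann <- fake_annotation("other_gene", 5)
  loc <- fake_localization(g$gene_id, "exported")
  expect_error(build_neighborhoods(g, ann, loc), g$gene_id[1])
})

test_that("the cluster-heme criterion flips exactly at 15", {
  g <- fake_genes("c1", c(1, 400), c(300, 900))
  loc <- fake_localization(g$gene_id, c("exported", "cytoplasmic"))
  for (partner in c(9, 10)) {
    ann <- fake_annotation(g$gene_id, c(5, partner))
    nb <- apply_criteria(build_neighborhoods(g, ann, loc))
    expect_equal(nb$total_hemes, 5L + partner)
    if (5 + partner >= 15) {
      expect_true(nb$passes)
      expect_length(nb$criteria_failed[[1]], 0L)
    } else {
      expect_false(nb$passes)
      expect_equal(nb$criteria_failed[[1]], "total_hemes")
    }
  }
})

test_that("the heme-rich criterion requires a >=4-heme protein even when totals pass", {
  g <- fake_genes("c1", seq(1, by = 400, length.out = 6),
                  seq(300, by = 400, length.out = 6))
  ann <- fake_annotation(g$gene_id, rep(3, 6))  # 18 hemes total, none heme-rich
  loc <- fake_localization(g$gene_id, c("exported", rep("cytoplasmic", 5)))
  nb <- apply_criteria(build_neighborhoods(g, ann, loc))
  expect_false(nb$passes)
  expect_equal(nb$criteria_failed[[1]], "heme_rich")
  expect_equal(nb$total_hemes, 18L)

  # toggling the gate off lets the same neighborhood pass
  cfg <- neighborhood_config(require_heme_rich = FALSE)
  nb2 <- apply_criteria(build_neighborhoods(g, ann, loc, cfg), cfg)
  expect_true(nb2$passes)
})

test_that("accessory genes are the non-MHC members and totals conserve hemes", {
  g <- fake_genes("c1", c(1, 400, 800), c(300, 700, 1200))
  ann <- fake_annotation(g$gene_id, c(10, 0, 5))
  loc <- fake_localization(g$gene_id, c("exported", "cytoplasmic", "cytoplasmic"))
  nb <- apply_criteria(build_neighborhoods(g, ann, loc))
  expect_equal(nb$accessory_genes[[1]], g$gene_id[2])
  expect_equal(nb$total_hemes, sum(ann$heme_count))
  expect_equal(nb$n_mhc, 2L)
})

test_that("assembly summary counts passing neighborhoods only", {
  g1 <- fake_genes("c1", c(1, 400), c(300, 900))
  g2 <- fake_genes("c2", c(1, 400), c(300, 900))
  g3 <- fake_genes("c3", 1, 300)
  g <- dplyr::bind_rows(g1, g2, g3)
  ann <- fake_annotation(g$gene_id, c(5, 10, 11, 11, 4))
  loc <- fake_localization(g$gene_id, c("exported", "cytoplasmic",
                                        "exported", "cytoplasmic",
                                        "exported"))
  nb <- apply_criteria(build_neighborhoods(g, ann, loc))
  s <- summarize_assembly(nb)
  expect_equal(s$n_neighborhoods_pass, 2L)   # 15 and 22 pass; 4 fails
  expect_equal(s$total_hemes_pass, 37L)
  expect_equal(s$n_high_heme_proteins, 2L)   # the two 11-heme members

  expect_identical(s, summarize_assembly(nb))

  none <- apply_criteria(build_neighborhoods(
    g3, fake_annotation(g3$gene_id, 0), fake_localization(g3$gene_id, "cytoplasmic")
  ))
  s0 <- summarize_assembly(none)
  expect_equal(nrow(s0), 0L)
})

test_that("neighborhoods are disjoint and conserve contig heme totals", {
  set.seed(301)
  for (i in 1:10) {
    specs <- replicate(sample(1:3, 1), {
      k <- sample(1:4, 1)
      cluster_spec(gene_heme_counts = sample(0:12, k, replace = TRUE),
                   exported_flags = sample(c(TRUE, FALSE), k, replace = TRUE))
    }, simplify = FALSE)
    sim <- simulate_assembly(specs, n_decoy_genes = 5, seed = 300 + i)
    res <- scan_genome(sim$genes)
    ids <- unlist(lapply(res$neighborhoods$members, `[[`, "gene_id"))
    expect_equal(anyDuplicated(ids), 0L)
    per_contig_nb <- vapply(res$neighborhoods$members,
                            function(m) sum(m$heme_count), integer(1))
    all_hemes <- sum(res$proteins$heme_count)
    expect_lte(sum(per_contig_nb), all_hemes)
  }
})

test_that("raising thresholds never increases the passing count", {
  sim <- simulate_assembly(
    list(cluster_spec(c(5, 10), c(TRUE, FALSE)),
         cluster_spec(c(4, 4, 4, 4), c(TRUE, TRUE, FALSE, FALSE)),
         cluster_spec(c(16), TRUE)),
    n_decoy_genes = 5, seed = 42
  )
  passes_at <- function(min_hemes, rich_min) {
    res <- scan_genome(sim$genes,
                       heme = heme_config(heme_rich_min = rich_min),
                       nbh = neighborhood_config(min_cluster_hemes = min_hemes))
    sum(res$neighborhoods$passes)
  }
  prev <- Inf
  for (m in seq(5, 40, by = 5)) {
    cur <- passes_at(m, 4)
    expect_lte(cur, prev)
    prev <- cur
  }
  prev <- Inf
  for (r in seq(1, 13, by = 2)) {
    cur <- passes_at(15, r)
    expect_lte(cur, prev)
    prev <- cur
  }
})
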