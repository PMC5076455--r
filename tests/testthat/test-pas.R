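de_from <- function(genes, cnr, btif) {
  data.frame(gene = genes, cnr = cnr, btif = btif)
}

test_that("compute_pas evaluates ARR * BTIF * log10(CNR) term by term", {
  pw <- list(pathway_id = "P", name = "P", par = 1L, members = c(X = 1))
  # single member, arr +1, btif 1, cnr 10 -> log10(10) = 1
  expect_equal(compute_pas(de_from("X", 10, 1L), pw), 1)
  # insignificant genes contribute nothing
  expect_equal(compute_pas(de_from("X", 10, 0L), pw), 0)
  # activator/repressor cancellation
  pw2 <- list(pathway_id = "P2", name = "P2", par = 1L,
              members = c(X = 1, Y = -1))
  expect_equal(compute_pas(de_from(c("X", "Y"), c(100, 100), c(1L, 1L)), pw2), 0)
  # log base is configurable
  expect_equal(compute_pas(de_from("X", 8, 1L), pw, log_base = 2), 3)
})

test_that("uncovered pathways score a flagged zero, not a measured zero", {
  pw <- list(pathway_id = "P", name = "P", par = 1L, members = c(ZZZ = 1))
  expect_warning(s <- compute_pas(de_from("X", 10, 1L), pw), "not measured")
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "no_coverage"))
  # a genuinely zero PAS carries no flag
  pw2 <- list(pathway_id = "P2", name = "P2", par = 1L, members = c(X = 1))
  s2 <- compute_pas(de_from("X", 1, 1L), pw2)
  expect_equal(as.numeric(s2), 0)
  expect_null(attr(s2, "no_coverage"))
})

test_that("compute_pas matches the naive term-by-term oracle on random inputs", {
  set.seed(13)
  for (i in 1:50) {
    genes <- paste0("G", 1:20)
    cnr <- runif(20, 0.05, 20)
    btif <- sample(0:1, 20, replace = TRUE)
    db <- random_pathway_db(5, genes)
    for (pw in db$pathways) {
      got <- compute_pas(de_from(genes, cnr, btif), pw, warn_missing = FALSE)
      want <- pas_oracle(genes, cnr, btif, pw)
      expect_equal(as.numeric(got), want$pas, tolerance = 1e-12)
    }
  }
})

test_that("PAS is additive over disjoint member subsets", {
  set.seed(17)
  genes <- paste0("G", 1:12)
  cnr <- runif(12, 0.1, 10)
  btif <- sample(0:1, 12, replace = TRUE)
  arr <- setNames(sample(c(1, -1, 0.5, -0.5), 12, replace = TRUE), genes)
  whole <- list(pathway_id = "W", name = "W", par = 1L, members = arr)
  left <- list(pathway_id = "L", name = "L", par = 1L, members = arr[1:6])
  right <- list(pathway_id = "R", name = "R", par = 1L, members = arr[7:12])
  de <- de_from(genes, cnr, btif)
  expect_equal(compute_pas(de, whole),
               compute_pas(de, left) + compute_pas(de, right),
               tolerance = 1e-12)
})

test_that("group profiles are antisymmetric in case/reference and scale-free", {
  set.seed(19)
  m <- matrix(runif(30 * 8, 1, 100), nrow = 30,
              dimnames = list(paste0("G", 1:30),
                              c(paste0("A", 1:4), paste0("B", 1:4))))
  db <- random_pathway_db(4, paste0("G", 1:30))
  fwd <- group_pas_profile(m, group_design("f", paste0("A", 1:4),
                                           paste0("B", 1:4)), db)
  rev <- group_pas_profile(m, group_design("r", paste0("B", 1:4),
                                           paste0("A", 1:4)), db)
  expect_equal(unname(unclass(fwd)[1, ]), unname(-unclass(rev)[1, ]),
               tolerance = 1e-12)
  # multiplying all intensities by a constant leaves every PAS unchanged
  scaled <- group_pas_profile(m * 37, group_design("f", paste0("A", 1:4),
                                                   paste0("B", 1:4)), db)
  expect_equal(unclass(fwd), unclass(scaled), tolerance = 1e-12)
})

test_that("a planted up-regulated pathway scores positive at group level", {
  set.seed(23)
  cfg <- sim_config(n_genes = 300, n_pathways = 4, genes_per_pathway = 10,
                    planted_pathways = c(PW01 = 2), seed = 23)
  db <- simulate_pathway_db(cfg)
  sim <- simulate_expression(cfg, db)
  prof <- suppressWarnings(group_pas_profile(sim$matrix, sim$design, db))
  expect_gt(prof[1, "PW01"], 0)
})

test_that("per-sample profiles reduce to per-sample ratios with group flags", {
  m <- tiny_matrix()
  db <- tiny_pathway_db()
  design <- tiny_design()
  prof <- per_sample_pas_profile(m, design, db)
  expect_equal(rownames(prof), design$case_ids)
  expect_equal(colnames(prof), c("MAPK", "SIRT"))
  de <- differential_expression(m, design)
  for (g in design$case_ids) {
    cnr_g <- per_sample_cnr(m, g, design$reference_ids)
    for (pid in colnames(prof)) {
      want <- pas_oracle(de$gene, as.numeric(cnr_g), de$btif,
                         db$pathways[[pid]])
      expect_equal(unname(prof[g, pid]), want$pas, tolerance = 1e-12)
    }
  }
  # mean of per-sample rows approximates the group PAS on homogeneous cases
  grp <- group_pas_profile(m, design, db)
  expect_equal(unname(colMeans(prof)), unname(unclass(grp)[1, ]),
               tolerance = 0.05)
})

test_that("a case sample equal to the reference mean scores zero everywhere", {
  m <- tiny_matrix()
  ref_mean <- rowMeans(m[, c("R1", "R2", "R3")])
  m <- cbind(m, CEQ = ref_mean)
  design <- group_design("d", c("C1", "C2", "C3", "CEQ"), c("R1", "R2", "R3"))
  prof <- per_sample_pas_profile(m, design, tiny_pathway_db())
  expect_equal(unname(unclass(prof)["CEQ", ]), c(0, 0), tolerance = 1e-12)
})

test_that("the zero-PAS filter removes exactly the all-zero rows", {
  values <- rbind(S1 = c(P1 = 1.2, P2 = -0.5),
                  S2 = c(P1 = 0, P2 = 0),
                  S3 = c(P1 = 0, P2 = 0.1))
  prof <- geroscope:::new_pas_profile(values, values == 999)
  expect_message(filt <- filter_zero_pas_samples(prof), "S2")
  expect_equal(rownames(filt), c("S1", "S3"))
  # no all-zero rows: identity
  filt2 <- filter_zero_pas_samples(filt)
  expect_equal(unclass(filt2), unclass(filt))
  # everything zero: error
  allz <- geroscope:::new_pas_profile(matrix(0, 2, 2,
                                             dimnames = list(c("a", "b"),
                                                             c("P1", "P2"))),
                                      matrix(FALSE, 2, 2))
  expect_error(filter_zero_pas_samples(allz), "zero PAS")
})

test_that("PAS profiles round-trip through TSV with their coverage flags", {
  dir <- withr::local_tempdir()
  m <- tiny_matrix()
  db <- tiny_pathway_db()
  prof <- per_sample_pas_profile(m, tiny_design(), db)
  write_pas_profile(prof, file.path(dir, "pas.tsv"), file.path(dir, "fl.tsv"))
  back <- read_pas_profile(file.path(dir, "pas.tsv"), file.path(dir, "fl.tsv"))
  expect_equal(unclass(back), unclass(prof))
  expect_equal(attr(back, "no_coverage"), attr(prof, "no_coverage"))
})
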