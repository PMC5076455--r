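test_that("node involvement is case-insensitive membership", {
  pw <- list(pathway_id = "P", name = "P", par = 1L,
             members = c(MAP2K1 = 1, DUSP1 = -1))
  expect_equal(nii("MAP2K1", pw), 1L)
  expect_equal(nii("map2k1", pw), 1L)
  expect_equal(nii("TP53", pw), 0L)
})

test_that("geroscore evaluates the DTI*NII*ARR*PAS*PAR sum", {
  db <- pathway_db(list(list(pathway_id = "P", name = "P", par = 1L,
                             members = c(T1 = 1))))
  pas <- c(P = 2)
  # inhibiting (DTI +1) an activator of an activated pro-aging pathway
  expect_equal(geroscore(list(drug_id = "d", targets = c(T1 = 1)), pas, db), 2)
  # activating the same target flips the sign
  expect_equal(geroscore(list(drug_id = "d", targets = c(T1 = -1)), pas, db), -2)
  # no targets, no score
  expect_equal(geroscore(list(drug_id = "d",
                              targets = setNames(numeric(0), character(0))),
                         pas, db), 0)
  # an anti-aging pathway (PAR -1) reverses the contribution
  db2 <- pathway_db(list(list(pathway_id = "P", name = "P", par = -1L,
                              members = c(T1 = 1))))
  expect_equal(geroscore(list(drug_id = "d", targets = c(T1 = 1)), pas, db2), -2)
  # a target outside every pathway contributes nothing
  expect_message(
    s <- geroscore(list(drug_id = "d", targets = c(NOPE = 1)), pas, db),
    "absent")
  expect_equal(s, 0)
})

test_that("geroscore matches the brute-force double-loop oracle", {
  set.seed(29)
  for (i in 1:100) {
    genes <- paste0("G", 1:15)
    db <- random_pathway_db(4, genes)
    pas <- setNames(rnorm(4, sd = 2), names(db$pathways))
    drug <- random_drug(genes)
    expect_equal(suppressMessages(geroscore(drug, pas, db)),
                 unname(geroscore_oracle(drug, pas, db)),
                 tolerance = 1e-12)
  }
})

test_that("geroscore is linear in PAS, additive in targets, odd in DTI", {
  set.seed(37)
  genes <- paste0("G", 1:12)
  db <- random_pathway_db(3, genes)
  pas <- setNames(rnorm(3), names(db$pathways))
  d1 <- list(drug_id = "a", targets = setNames(c(1, -1), genes[1:2]))
  d2 <- list(drug_id = "b", targets = setNames(c(1, 1), genes[3:4]))
  both <- list(drug_id = "ab", targets = c(d1$targets, d2$targets))
  gs <- function(d, p) suppressMessages(geroscore(d, p, db))
  expect_equal(gs(d1, pas * 3), 3 * gs(d1, pas), tolerance = 1e-12)
  expect_equal(gs(both, pas), gs(d1, pas) + gs(d2, pas), tolerance = 1e-12)
  neg <- list(drug_id = "n", targets = -d1$targets)
  expect_equal(gs(neg, pas), -gs(d1, pas), tolerance = 1e-12)
})

test_that("score tables aggregate, rank and break ties lexicographically", {
  db <- pathway_db(list(list(pathway_id = "P", name = "P", par = 1L,
                             members = c(T1 = 1, T2 = -1))))
  prof <- geroscope:::new_pas_profile(
    matrix(c(2, 4), ncol = 1, dimnames = list(c("S1", "S2"), "P")),
    matrix(FALSE, 2, 1))
  drugs <- drug_db(list(
    list(drug_id = "zeta", targets = c(T1 = 1)),
    list(drug_id = "alpha", targets = c(T1 = 1)),   # exact tie with zeta
    list(drug_id = "mid", targets = c(T2 = 1))))
  tab <- geroscore_table(drugs, prof, db)
  # per-sample scores: T1 drugs 2 and 4, aggregate 3; mid -2 and -4
  expect_equal(tab$drug_id, c("alpha", "zeta", "mid"))
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$aggregate_score, c(3, 3, -3))
  expect_equal(unname(unlist(tab[tab$drug_id == "mid", c("S1", "S2")])),
               c(-2, -4))
  expect_equal(tab$aggregate_score,
               rowMeans(as.matrix(tab[, c("S1", "S2")])),
               ignore_attr = TRUE)
  # single sample, single drug equals a direct geroscore() call
  prof1 <- geroscope:::new_pas_profile(
    matrix(2, 1, 1, dimnames = list("S1", "P")), matrix(FALSE, 1, 1))
  tab1 <- geroscore_table(drug_db(list(list(drug_id = "zeta",
                                            targets = c(T1 = 1)))), prof1, db)
  expect_equal(tab1$aggregate_score,
               geroscore(list(drug_id = "zeta", targets = c(T1 = 1)),
                         c(P = 2), db))
  # median aggregation is available
  tabm <- geroscore_table(drugs, prof, db, aggregate = "median")
  expect_equal(tabm$aggregate_score[tabm$drug_id == "mid"], -3)
  expect_error(geroscore_table(drug_db(list()), prof, db), "empty")
})

test_that("vectorized table scores match per-drug geroscore on random data", {
  set.seed(43)
  genes <- paste0("G", 1:20)
  db <- random_pathway_db(5, genes)
  values <- matrix(rnorm(3 * 5), nrow = 3,
                   dimnames = list(paste0("S", 1:3), names(db$pathways)))
  prof <- geroscope:::new_pas_profile(values, values == 999)
  drugs <- drug_db(lapply(1:8, function(i) {
    d <- random_drug(genes); d$drug_id <- sprintf("D%02d", i); d
  }))
  tab <- geroscore_table(drugs, prof, db)
  for (i in seq_len(nrow(tab))) {
    for (s in paste0("S", 1:3)) {
      expect_equal(tab[i, s],
                   unname(geroscore_oracle(drugs$drugs[[tab$drug_id[i]]],
                                           values[s, ], db)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(sort(tab$rank), 1:8)
})

test_that("shortlist returns the top n drugs in rank order", {
  db <- pathway_db(list(list(pathway_id = "P", name = "P", par = 1L,
                             members = c(T1 = 1))))
  prof <- geroscope:::new_pas_profile(
    matrix(1, 1, 1, dimnames = list("S1", "P")), matrix(FALSE, 1, 1))
  drugs <- drug_db(lapply(1:5, function(i)
    list(drug_id = sprintf("D%d", i),
         targets = setNames(if (i %% 2) 1 else -1, "T1"))))
  tab <- geroscore_table(drugs, prof, db)
  expect_equal(shortlist(tab, 5), tab$drug_id)
  expect_equal(shortlist(tab, 1), tab$drug_id[1])
  expect_error(shortlist(tab, 6), "shortlist")
})

test_that("multi-dataset combination averages z-scored aggregates", {
  t1 <- data.frame(drug_id = c("a", "b", "c"),
                   aggregate_score = c(3, 1, -1), rank = 1:3)
  t2 <- data.frame(drug_id = c("a", "b", "c"),
                   aggregate_score = c(30, -10, 10), rank = c(1, 3, 2))
  comb <- combine_geroscore_tables(list(t1, t2))
  z1 <- scale(t1$aggregate_score)[, 1]
  z2 <- scale(t2$aggregate_score)[, 1]
  want <- (z1 + z2) / 2
  expect_equal(comb$combined_score[match(c("a", "b", "c"), comb$drug_id)],
               want, ignore_attr = TRUE)
  expect_equal(comb$drug_id[comb$rank == 1], "a")
})
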