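# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A small deterministic expression matrix: 6 genes x 6 samples.
tiny_matrix <- function() {
  m <- matrix(c(10, 11, 12, 20, 21, 22,   # GA: case = 2x reference
                30, 31, 29, 30, 31, 29,   # GB: flat
                5, 6, 7, 50, 60, 70,      # GC: case = 10x reference
                8, 8, 8, 8, 8, 8,         # GD: constant
                100, 90, 110, 10, 9, 11,  # GE: case = 0.1x reference
                1, 2, 1, 2, 1, 2),        # GF: noise around 1.5
              nrow = 6, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC", "GD", "GE", "GF"),
                              c("R1", "R2", "R3", "C1", "C2", "C3")))
  m
}

tiny_design <- function() {
  group_design("case_vs_ref", case_ids = c("C1", "C2", "C3"),
               reference_ids = c("R1", "R2", "R3"))
}

tiny_pathway_db <- function() {
  pathway_db(list(
    list(pathway_id = "MAPK", name = "MAPK signaling", par = 1L,
         members = c(GA = 1, GC = 0.5, GE = -1)),
    list(pathway_id = "SIRT", name = "Sirtuin axis", par = -1L,
         members = c(GB = 1, GF = -0.5))))
}

tiny_drug_db <- function() {
  drug_db(list(
    list(drug_id = "inhibA", targets = c(GA = 1)),
    list(drug_id = "actE", targets = c(GE = -1)),
    list(drug_id = "none", targets = setNames(numeric(0), character(0)))))
}

# Random pathway db over a gene universe, for property tests.
random_pathway_db <- function(n_pathways, genes, max_members = 6) {
  pathway_db(lapply(seq_len(n_pathways), function(i) {
    k <- sample(seq_len(min(max_members, length(genes))), 1)
    list(pathway_id = sprintf("P%02d", i), name = sprintf("P%02d", i),
         par = sample(c(-1L, 1L), 1),
         members = setNames(sample(c(1, -1, 0.5, -0.5), k, replace = TRUE),
                            sample(genes, k)))
  }))
}

random_drug <- function(genes, max_targets = 5) {
  k <- sample(seq_len(min(max_targets, length(genes))), 1)
  list(drug_id = "D", targets = setNames(sample(c(-1, 1), k, replace = TRUE),
                                         sample(genes, k)))
}

# Brute-force oracles ------------------------------------------------------

# PAS by its term-by-term definition, one explicit loop over members.
pas_oracle <- function(genes, cnr, btif, pathway, log_base = 10) {
  total <- 0
  covered <- FALSE
  for (g in names(pathway$members)) {
    i <- match(g, genes)
    if (is.na(i) || is.na(cnr[i]) || is.na(btif[i])) next
    covered <- TRUE
    total <- total + pathway$members[[g]] * btif[i] * log(cnr[i], log_base)
  }
  list(pas = total, covered = covered)
}

# GeroScore by the printed double sum over targets t and pathways p.
geroscore_oracle <- function(drug, pas_row, db) {
  total <- 0
  for (t in names(drug$targets)) {
    inner <- 0
    for (p in db$pathways) {
      if (!toupper(t) %in% names(p$members)) next      # NII = 0
      inner <- inner + p$members[[toupper(t)]] * pas_row[[p$pathway_id]] * p$par
    }
    total <- total + drug$targets[[t]] * inner
  }
  total
}

# Benjamini-Hochberg by the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
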