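test_that("sex-bias calls follow the significance-and-direction rule", {
  r <- stub_result(log2FC = c(2, -1, 2, 0.5),
                   significant = c(TRUE, TRUE, FALSE, FALSE))
  r$padj <- c(0.01, 0.02, 0.2, 0.6)
  expect_equal(call_sex_bias(r), c("male", "female", "neutral", "neutral"))
})

test_that("species-by-sex grouping matches the 18-combination truth table", {
  combos <- expand.grid(sp = c(1, -1, 0), sx = c(1, -1, 0), it = c(1, 0))
  species <- stub_result(ifelse(combos$sp == 0, 0.1, combos$sp * 2),
                         combos$sp != 0)
  sex <- stub_result(ifelse(combos$sx == 0, -0.1, combos$sx * 2),
                     combos$sx != 0)
  inter <- stub_result(1, combos$it == 1)
  got <- call_species_sex_group(species, sex, inter)
  oracle <- apply(combos, 1, function(r) {
    l1 <- if (r["sp"] == 1) "N" else if (r["sp"] == -1) "B" else "C"
    l2 <- if (r["sx"] == 1) "M" else if (r["sx"] == -1) "F" else "N"
    l3 <- if (r["it"] == 1) "I" else "N"
    paste(l1, l2, l3, sep = "-")
  })
  expect_equal(got, unname(oracle))
  expect_equal(got[combos$sp == 0 & combos$sx == 0 & combos$it == 0], "C-N-N")
})

test_that("inheritance calls partition the full contrast space", {
  grid <- expand.grid(s1 = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                      sp = c(TRUE, FALSE), d1 = c(1.2, -0.8), d2 = c(0.6, -1.4))
  f1_cbr <- stub_result(grid$d1, grid$s1)
  f1_cni <- stub_result(grid$d2, grid$s2)
  parents <- stub_result(1, grid$sp)
  got <- call_inheritance(f1_cbr, f1_cni, parents)
  # hand-enumerated oracle following the published taxonomy
  oracle <- mapply(function(s1, s2, sp, d1, d2) {
    if (!s1 && !s2) return("no_change")
    if (s1 && s2 && d1 > 0 && d2 > 0) return("overdominant")
    if (s1 && s2 && d1 < 0 && d2 < 0) return("underdominant")
    if (s1 && s2 && sp && sign(d1) != sign(d2)) return("additive")
    if (!s1 && s2 && sp) return("dominant_CBR")
    if (s1 && !s2 && sp) return("dominant_CNI")
    "ambiguous"
  }, grid$s1, grid$s2, grid$sp, grid$d1, grid$d2)
  expect_equal(got$category, unname(oracle))
  # every gene gets exactly one category from the closed set
  expect_true(all(got$category %in% hybridex:::INHERITANCE_CATEGORIES))
})

test_that("misexpression distance is the Euclidean norm", {
  expect_equal(expression_distance(0, 0), 0)
  expect_equal(expression_distance(3, 4), 5)
  expect_equal(expression_distance(-1, 1), sqrt(2))
  expect_equal(expression_distance(1, -1), sqrt(2))
})

test_that("cis/trans calls match the exhaustive significance truth table", {
  grid <- expand.grid(sP = c(TRUE, FALSE), sA = c(TRUE, FALSE),
                      sT = c(TRUE, FALSE), dA = c(1, -1), dT = c(1, -1))
  P <- stub_result(2, grid$sP)
  A <- stub_result(grid$dA * 1.5, grid$sA)
  T_ <- stub_result(grid$dT * 1.2, grid$sT)
  got <- call_cis_trans(P, A, T_)
  oracle <- mapply(function(sP, sA, sT, dA, dT) {
    if (!sP && !sA && !sT) return("conserved")
    if (sA && !sT && sP) return("cis_only")
    if (!sA && sT && sP) return("trans_only")
    if (sA && sT && dA == dT) return("cis_plus_trans")
    if (sA && sT && dA != dT && sP) return("cis_x_trans_compensatory")
    if (sA && sT && dA != dT && !sP) return("compensatory")
    "ambiguous"
  }, grid$sP, grid$sA, grid$sT, grid$dA, grid$dT)
  expect_equal(got$category, unname(oracle))
  # spot checks straight from the scheme
  one <- function(sP, sA, sT, dA = 1, dT = 1)
    call_cis_trans(stub_result(2, sP), stub_result(dA, sA),
                   stub_result(dT, sT))$category
  expect_equal(one(TRUE, TRUE, FALSE), "cis_only")
  expect_equal(one(FALSE, TRUE, TRUE, dA = 1, dT = -1), "compensatory")
  expect_equal(one(FALSE, TRUE, FALSE), "ambiguous")  # significant ASE only
})

test_that("species-label swap maps calls symmetrically", {
  cfg <- sim_config(n_genes = 300, seed = 59)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  flip <- function(r) { r$log2FC <- -r$log2FC; r$direction <- -r$direction; r }
  calls <- call_cis_trans(reg$P, reg$A, reg$T)
  swapped <- call_cis_trans(flip(reg$P), flip(reg$A), flip(reg$T))
  expect_equal(swapped$category, calls$category)
  expect_equal(swapped$A, -calls$A)

  f1_cbr <- stub_result(c(0.1, 2), c(FALSE, TRUE))
  f1_cni <- stub_result(c(2, 0.1), c(TRUE, FALSE))
  parents <- stub_result(c(2, -2), c(TRUE, TRUE))
  inh <- call_inheritance(f1_cbr, f1_cni, parents)
  inh_sw <- call_inheritance(f1_cni, f1_cbr, flip(parents))
  map <- c(dominant_CBR = "dominant_CNI", dominant_CNI = "dominant_CBR")
  expect_equal(inh_sw$category, unname(map[inh$category]))
})

test_that("hemizygous-X male scheme matches its truth table", {
  inh_cats <- hybridex:::INHERITANCE_CATEGORIES
  grid <- expand.grid(sP = c(TRUE, FALSE), inh = inh_cats,
                      stringsAsFactors = FALSE)
  P <- stub_result(1.5, grid$sP)
  inheritance <- data.frame(gene = P$gene, category = grid$inh, d = 1)
  got <- call_x_male(P, inheritance)
  oracle <- mapply(function(sP, inh) {
    if (!sP && inh == "no_change") return("conserved")
    if (!sP && inh %in% c("overdominant", "underdominant"))
      return("compensatory_cis_trans")
    if (sP && inh == "dominant_CNI") return("cis_only_star")
    if (sP && inh == "dominant_CBR") return("trans_only_star")
    "other"
  }, grid$sP, grid$inh)
  expect_equal(got, unname(oracle))
  expect_error(call_x_male(P, inheritance, x_linked = rep(FALSE, nrow(P))),
               "X-linked")
})

test_that("hermaphrodite reconciliation flags the right genes", {
  bias_main <- c(g1 = "male", g2 = "male", g3 = "female", g4 = "male")
  bias_ref <- c(g1 = "male", g2 = "neutral", g3 = "male", g4 = "male")
  cross <- stub_result(c(2, 2, 2, -1), c(TRUE, TRUE, TRUE, TRUE),
                       gene = paste0("g", 1:4))
  # g1: male in both + up in hermaphrodite -> flagged
  # g2: neutral in reference -> no; g3: not male in main -> no
  # g4: male in both but higher in reference -> no
  expect_equal(reconcile_hermaphrodite(bias_main, bias_ref, cross), "g1")
  expect_equal(reconcile_hermaphrodite(bias_main, bias_ref, cross[0, ]),
               character(0))
})
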