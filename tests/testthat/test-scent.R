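toy_voc <- function() {
  data.frame(species = paste0("sp", 1:6),
             ecotype = rep(c("forest", "gap"), each = 3),
             A = c(5, 4, 3, 2, 1, 6),      # everywhere
             B = c(3, 3, 3, 3, 0, 0),      # 4 species
             C = c(1, 1, 1, 1, 1, 0),      # exactly 5
             D = c(0, 0, 0, 0, 0, 2))      # 1 species
}

test_that("prevalence filter drops below-threshold compounds only", {
  m <- toy_voc()
  f <- prevalence_filter(m, min_samples = 5)
  expect_true("A" %in% names(f))
  expect_true("C" %in% names(f))          # exactly at threshold: retained
  expect_false("B" %in% names(f))         # 4 < 5: dropped
  expect_false("D" %in% names(f))
  expect_equal(attr(f, "dropped"), c("B", "D"))
  expect_equal(f$species, m$species)      # row order preserved

  # surviving column count equals an independent recount
  v <- generate_voc_matrix(seed = 21)
  f2 <- prevalence_filter(v, min_samples = 5)
  manual <- sum(vapply(setdiff(names(v), c("species", "ecotype")),
                       function(cp) sum(v[[cp]] > 0) >= 5, logical(1)))
  expect_equal(length(setdiff(names(f2), c("species", "ecotype"))), manual)
})

test_that("top-k ranking truncates at k and at the last nonzero entry", {
  m <- data.frame(species = "s1", ecotype = "gap", A = 5, B = 3, C = 1)
  expect_equal(top_k_compounds(m, k = 2)$s1, c("A", "B"))
  expect_equal(top_k_compounds(m, k = 10)$s1, c("A", "B", "C"))
  m0 <- data.frame(species = "s1", ecotype = "gap", A = 5, B = 0, C = 1)
  expect_equal(top_k_compounds(m0, k = 10)$s1, c("A", "C"))

  # ties at rank k break lexicographically
  mt <- data.frame(species = "s1", ecotype = "gap", Zed = 3, Ant = 3, Mid = 9)
  expect_equal(top_k_compounds(mt, k = 2)$s1, c("Mid", "Ant"))
})

test_that("common-compound selection ranks by prevalence deterministically", {
  same <- list(s1 = c("A", "B"), s2 = c("A", "B"), s3 = c("A", "B"))
  cs <- common_compounds(same, n_target = 2)
  expect_equal(cs$compound, c("A", "B"))
  expect_equal(cs$prevalence, c(3L, 3L))

  disjoint <- list(s1 = "A", s2 = "B", s3 = "C")
  cs2 <- common_compounds(disjoint, min_prevalence = 1)
  expect_true(all(cs2$prevalence == 1L))

  # constructed matrix where exactly 15 compounds are shared widely
  v <- generate_voc_matrix(seed = 22)
  topk <- top_k_compounds(prevalence_filter(v), k = 20)
  cs3 <- common_compounds(topk, n_target = 15)
  expect_equal(nrow(cs3), 15L)
  # the 15 designed-common compounds dominate every species' top-20
  # (abundance noise can push an individual compound out of a list or two)
  expect_setequal(cs3$compound, sprintf("VOC%03d", 1:15))
  expect_true(all(cs3$prevalence >= 19L))
})

test_that("the three analysis datasets are consistent with direct sums", {
  single <- data.frame(species = "s1", ecotype = "gap", A = 2, B = 3)
  ds <- build_scent_datasets(single, c("A", "B"))
  expect_equal(ds$total_emission$value, 5)
  expect_equal(ds$n_compounds$value, 2)

  zero <- data.frame(species = "s1", ecotype = "gap", A = 0, B = 0)
  ds0 <- build_scent_datasets(zero, "A")
  expect_equal(ds0$total_emission$value, 0)
  expect_equal(ds0$n_compounds$value, 0)

  v <- generate_voc_matrix(n_compounds = 40, seed = 23)
  ds2 <- build_scent_datasets(v, sprintf("VOC%03d", 1:15))
  manual <- vapply(seq_len(nrow(v)), function(i)
    sum(as.numeric(v[i, setdiff(names(v), c("species", "ecotype"))])),
    numeric(1))
  expect_equal(ds2$total_emission$value, manual)
  expect_error(build_scent_datasets(v, "nope"), "not in matrix")
})

test_that("filtering commutes with top-k on surviving columns", {
  v <- generate_voc_matrix(n_compounds = 60, seed = 24)
  f <- prevalence_filter(v, min_samples = 5)
  t1 <- top_k_compounds(f, k = 10)
  surviving <- setdiff(names(f), c("species", "ecotype"))
  t2 <- lapply(top_k_compounds(v, k = 60), function(lst)
    head(lst[lst %in% surviving], 10))
  expect_equal(t1, t2[names(t1)])

  # dataset totals invariant to column permutation
  comp <- setdiff(names(v), c("species", "ecotype"))
  vp <- v[, c("species", "ecotype", sample(comp))]
  expect_equal(build_scent_datasets(vp, "VOC001")$total_emission$value,
               build_scent_datasets(v, "VOC001")$total_emission$value)
})
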