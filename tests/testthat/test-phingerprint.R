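# phingerprint assembly, clustering, archetype recovery, metadata tests

folds_from_matrix <- function(m, traits, intervals, genos) {
  tidyr::expand_grid(trait = traits, interval = intervals,
                     genotype = genos) |>
    dplyr::mutate(log2fc = as.vector(t(m)), clipped = FALSE)
}

test_that("matrix assembly: 33 rows, ordering, z-rows and missing features", {
  genos <- sprintf("G%02d", 1:6)
  traits <- sort(trait_baselines()$trait)
  ivs <- c("early_recovery", "late_recovery")
  set.seed(10)
  vals <- matrix(rnorm(16 * 2 * 6), 32, 6)
  folds <- folds_from_matrix(vals, traits, ivs, genos)
  nec <- tibble::tibble(genotype = genos, feature = "necrosis_d13",
                        value = rnorm(6))
  m <- build_phingerprint(folds, nec)
  expect_equal(dim(m), c(33L, 6L))
  expect_equal(rownames(m)[33], "necrosis_d13")
  # trait alphabetical within interval blocks
  expect_equal(rownames(m)[1:16], paste(traits, "early_recovery", sep = "."))
  expect_equal(unname(abs(rowMeans(m))), rep(0, 33), tolerance = 1e-9)
  expect_equal(apply(m, 1, sd), rep(1, 33), ignore_attr = TRUE,
               tolerance = 1e-9)

  raw <- build_phingerprint(folds, nec, normalize = "none")
  expect_equal(raw["necrosis_d13", ], setNames(nec$value, genos))
  # removing one genotype leaves the remaining raw columns unchanged
  sub <- build_phingerprint(folds[folds$genotype != "G03", ],
                            nec[nec$genotype != "G03", ],
                            normalize = "none")
  expect_equal(sub, raw[, colnames(sub)], ignore_attr = TRUE)
  expect_error(build_phingerprint(folds[-1, ], nec),
               class = "coldpheno_missing_feature")
})

test_that("clustering separates constructed groups and handles degeneracy", {
  # two well-separated column groups
  set.seed(2)
  m <- cbind(matrix(rnorm(10 * 4, 5, 0.1), 10),
             matrix(rnorm(10 * 4, -5, 0.1), 10))
  dimnames(m) <- list(paste0("f", 1:10), sprintf("G%02d", 1:8))
  cl <- hcluster_phingerprint(m)
  expect_equal(cl$chosen_k, 2L)
  expect_equal(unname(cl$assignments[1:4]), rep(1L, 4))
  expect_equal(unname(cl$assignments[5:8]), rep(2L, 4))
  # identical columns: degenerate result with one cluster
  same <- matrix(1, 5, 4, dimnames = list(paste0("f", 1:5), letters[1:4]))
  expect_warning(dg <- hcluster_phingerprint(same),
                 class = "coldpheno_degenerate_clustering")
  expect_equal(dg$chosen_k, 1L)
  expect_equal(unname(dg$assignments), rep(1L, 4))
  # column permutation changes nothing (up to relabeling)
  perm <- m[, c(3, 7, 1, 5, 2, 8, 4, 6)]
  clp <- hcluster_phingerprint(perm)
  expect_equal(mclust::adjustedRandIndex(clp$assignments[colnames(m)],
                                         cl$assignments), 1)
})

test_that("dendrogram merge heights match the naive agglomerative oracle", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(rnorm(6 * 8), 6, 8,
                                       dimnames = list(paste0("f", 1:6),
                                                       paste0("g", 1:8))))
    cl <- hcluster_phingerprint(m)
    d <- dist(t(m))
    expect_equal(sort(cl$hclust$height),
                 sort(oracle_linkage_heights(d, "complete")))
    cls <- hcluster_phingerprint(m, linkage = "single")
    expect_equal(sort(cls$hclust$height),
                 sort(oracle_linkage_heights(d, "single")))
  }
})

test_that("row z-normalization makes cluster choice scale-invariant", {
  set.seed(14)
  raw <- cbind(matrix(rnorm(8 * 5, 3, 0.2), 8),
               matrix(rnorm(8 * 5, -3, 0.2), 8))
  dimnames(raw) <- list(paste0("f", 1:8), sprintf("G%02d", 1:10))
  zs <- function(m) (m - rowMeans(m)) / apply(m, 1, sd)
  rescaled <- raw * (1:8) + 100 * (8:1)   # per-feature affine rescale
  a <- hcluster_phingerprint(zs(raw))
  b <- hcluster_phingerprint(zs(rescaled))
  expect_equal(b$chosen_k, a$chosen_k)
  expect_equal(mclust::adjustedRandIndex(a$assignments, b$assignments), 1)
})

test_that("archetype recovery scores perfect, random and merged assignments", {
  truth <- setNames(rep(c("a", "b", "c"), each = 40 / 4 * 0 + 13)[1:39],
                    sprintf("G%02d", 1:39))
  perfect <- setNames(as.integer(factor(truth)), names(truth))
  expect_equal(recover_archetypes(truth, perfect), 1)
  random <- withr::with_seed(5, setNames(sample(1:3, 39, TRUE),
                                         names(truth)))
  expect_lt(abs(recover_archetypes(truth, random)), 0.15)
  merged <- perfect
  merged[merged == 3L] <- 2L
  expect_lt(recover_archetypes(truth, merged), 1)
  expect_error(recover_archetypes(truth,
                                  setNames(1:3, c("X1", "X2", "X3"))))
})

test_that("latitude associations: identity, nulls and affine invariance", {
  genos <- sprintf("G%02d", 1:40)
  lat <- withr::with_seed(8, setNames(runif(40, 32, 48), genos))
  m <- matrix(lat, 1, 40, dimnames = list("f_lat", genos))
  r <- latitude_association(m, lat)
  expect_equal(r$r, 1)
  # affine rescaling of latitude leaves r untouched
  expect_equal(latitude_association(m, 3 * lat - 100)$r, 1)
  # independent features: almost all associations are null
  null_m <- withr::with_seed(4, matrix(rnorm(33 * 40), 33, 40,
                                       dimnames = list(paste0("f", 1:33),
                                                       genos)))
  la <- latitude_association(null_m, lat)
  expect_gte(mean(la$p > 0.05), 0.9)
  # constant features are reported missing
  cm <- rbind(null_m[1:2, ], f_const = rep(1, 40))
  expect_true(is.na(latitude_association(cm, lat)$r[3]))
})

test_that("newick export and tidiers expose the clustering faithfully", {
  set.seed(3)
  m <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("g", 1:6)))
  cl <- hcluster_phingerprint(m)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  export_newick(cl, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, colnames(m))
  td <- tidy(cl)
  expect_equal(nrow(td), 6)
  expect_setequal(td$genotype, colnames(m))
  gl <- glance(cl)
  expect_equal(gl$chosen_k, cl$chosen_k)
  expect_equal(gl$n_genotypes, 6)
})
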