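# phingerprint assembly and hierarchical clustering of genotype
# cold-response profiles

#' Assemble the phingerprint matrix
#'
#' Rows are trait-by-interval log2 fold-change features (trait
#' alphabetical within interval order of appearance), with optional
#' necrosis features appended last; columns are genotypes in
#' lexicographic order. Missing genotype/feature combinations are an
#' error, never imputed. Row z-normalization (the default) gives every
#' feature mean 0 and sd 1 across genotypes.
#'
#' @param folds Output of [log2_fold_change()].
#' @param necrosis Optional output of [necrosis_summary()] (or any
#'   tibble with `genotype`, `feature`, `value`).
#' @param normalize `"row_z"` or `"none"`.
#' @return A numeric matrix (features x genotypes) of class
#'   `phingerprint`, with a `normalize` attribute.
#' @export
build_phingerprint <- function(folds, necrosis = NULL,
                               normalize = c("row_z", "none")) {
  normalize <- match.arg(normalize)
  intervals <- unique(folds$interval)
  traits <- sort(unique(folds$trait))
  genotypes <- sort(unique(folds$genotype))
  feat <- tidyr::expand_grid(interval = intervals, trait = traits)
  feat$feature <- paste(feat$trait, feat$interval, sep = ".")

  long <- dplyr::mutate(folds,
                        feature = paste(.data$trait, .data$interval,
                                        sep = "."))
  long <- long[c("genotype", "feature", "value" = "log2fc")]
  names(long)[3] <- "value"
  if (!is.null(necrosis)) {
    long <- dplyr::bind_rows(long,
                             necrosis[c("genotype", "feature", "value")])
    feat <- dplyr::bind_rows(feat,
                             tibble(interval = NA, trait = NA,
                                    feature = unique(necrosis$feature)))
  }

  full <- tidyr::expand_grid(feature = feat$feature, genotype = genotypes)
  merged <- dplyr::left_join(full, long, by = c("feature", "genotype"))
  gaps <- merged[is.na(merged$value), ]
  if (nrow(gaps)) {
    abort(sprintf("missing phingerprint value(s): %s",
                  paste(utils::head(paste(gaps$genotype, gaps$feature,
                                          sep = "/"), 5),
                        collapse = ", ")),
          class = "coldpheno_missing_feature")
  }
  m <- matrix(merged$value, nrow = nrow(feat), byrow = TRUE,
              dimnames = list(feat$feature, genotypes))
  if (normalize == "row_z") {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      abort(sprintf("constant feature row(s) cannot be z-normalized: %s",
                    paste(rownames(m)[sds == 0], collapse = ", ")),
            class = "coldpheno_missing_feature")
    }
    m <- (m - rowMeans(m)) / sds
  }
  structure(m, normalize = normalize, class = c("phingerprint", "matrix"))
}

#' Hierarchically cluster genotypes by phingerprint
#'
#' Agglomerative clustering of genotype columns (Euclidean distance,
#' complete linkage by default — the defaults of the heatmap tooling
#' this workflow mirrors). The tree is cut at every `k` in `k_scan`;
#' the chosen cluster count maximizes the mean silhouette width, with
#' ties broken toward the smallest `k`. If all pairwise distances are
#' zero the result is degenerate: one cluster, with a
#' `coldpheno_degenerate_clustering` warning.
#'
#' @param x A [build_phingerprint()] matrix (or any features x
#'   genotypes matrix).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Linkage method for [stats::hclust()].
#' @param k_scan Candidate cluster counts (default 2–6).
#' @return An object of class `cold_clusters`: the `hclust` tree,
#'   a `silhouette` tibble (k, mean silhouette), `chosen_k`, and the
#'   `assignments` at the chosen k (named integer vector).
#' @export
hcluster_phingerprint <- function(x, metric = "euclidean",
                                  linkage = "complete", k_scan = 2:6) {
  m <- unclass(x)
  if (ncol(m) < 2) abort("at least 2 genotypes are required")
  m <- m[, order(colnames(m)), drop = FALSE]   # deterministic tie order
  d <- dist(t(m), method = metric)
  if (max(d) <= 1e-12) {
    warn("all genotype profiles identical: degenerate clustering",
         class = "coldpheno_degenerate_clustering")
    return(structure(list(
      hclust = NULL, metric = metric, linkage = linkage,
      silhouette = tibble(k = integer(), mean_silhouette = double()),
      chosen_k = 1L,
      assignments = setNames(rep(1L, ncol(m)), colnames(m))
    ), class = "cold_clusters"))
  }
  hc <- hclust(d, method = linkage)
  k_scan <- k_scan[k_scan >= 2 & k_scan < ncol(m)]
  sil <- purrr::map_dfr(k_scan, function(k) {
    cut <- cutree(hc, k)
    sw <- cluster::silhouette(cut, d)
    tibble(k = k, mean_silhouette = mean(sw[, "sil_width"]))
  })
  chosen <- sil$k[which.max(sil$mean_silhouette)]   # ties: smallest k
  structure(list(
    hclust = hc, metric = metric, linkage = linkage,
    silhouette = sil, chosen_k = chosen,
    assignments = cutree(hc, chosen)
  ), class = "cold_clusters")
}

#' @export
print.cold_clusters <- function(x, ...) {
  cat(sprintf("<cold_clusters> %d genotypes, %s/%s; chosen k = %d\n",
              length(x$assignments), x$metric, x$linkage, x$chosen_k))
  print(x$silhouette)
  invisible(x)
}

#' Score cluster recovery against generator truth
#'
#' Adjusted Rand index between the clustering assignments and the true
#' archetype labels of a synthetic panel.
#'
#' @param truth Named vector of archetype labels, or a tibble with
#'   `genotype` and `archetype` columns (e.g. a [genotype_panel()]).
#' @param clusters A [hcluster_phingerprint()] result (or a named
#'   assignment vector).
#' @return The adjusted Rand index (1 = perfect recovery, ~0 = chance).
#' @export
recover_archetypes <- function(truth, clusters) {
  if (is.data.frame(truth)) {
    truth <- setNames(truth$archetype, truth$genotype)
  }
  assign <- if (inherits(clusters, "cold_clusters")) clusters$assignments
            else clusters
  common <- intersect(names(truth), names(assign))
  if (!length(common)) {
    abort("no genotypes shared between truth and assignments")
  }
  mclust::adjustedRandIndex(truth[common], assign[common])
}

#' Latitude (metadata) association of phingerprint features
#'
#' Pearson correlation and two-sided p-value, across genotypes, between
#' each feature row and a genotype-level covariate such as latitude of
#' origin. Constant feature rows yield missing results.
#'
#' @param x A phingerprint matrix (features x genotypes).
#' @param latitudes Named numeric vector, or a tibble with `genotype`
#'   and `latitude_deg` columns.
#' @return Tibble with `feature`, `r`, `p` per feature.
#' @export
latitude_association <- function(x, latitudes) {
  if (is.data.frame(latitudes)) {
    latitudes <- setNames(latitudes$latitude_deg, latitudes$genotype)
  }
  if (!all(colnames(x) %in% names(latitudes))) {
    abort("latitude missing for some genotypes")
  }
  lat <- latitudes[colnames(x)]
  purrr::map_dfr(rownames(x), function(f) {
    v <- x[f, ]
    if (sd(v) == 0 || sd(lat) == 0) {
      return(tibble(feature = f, r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(v, lat)
    tibble(feature = f, r = unname(ct$estimate), p = ct$p.value)
  })
}

#' Export the genotype dendrogram as newick
#'
#' @param clusters A [hcluster_phingerprint()] result.
#' @param path Output file path.
#' @export
export_newick <- function(clusters, path) {
  if (is.null(clusters$hclust)) abort("degenerate clustering has no tree")
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}
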