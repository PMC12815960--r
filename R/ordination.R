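# Family-level community matrix, non-metric multidimensional scaling on
# Bray-Curtis dissimilarities (via vegan), and environmental vector fitting.
# Prey families are the points; ICES rectangles are the composition axes.

#' Build the family-by-rectangle community matrix
#'
#' Sums prey abundance per family and rectangle and computes per-family
#' covariates: abundance-weighted mean individual mass, mean temperature,
#' mean fishing effort (over rows where effort matched), modal size class,
#' and total abundance. Families below `min_abundance` total individuals are
#' dropped with a message.
#'
#' @param matched Matched prey-item-level tibble (needs `prey_family`,
#'   `prey_count`, `prey_indiv_mass_g`, `ices_rectangle`, `sst_c`, and
#'   optionally `effort_hours`).
#' @param min_abundance Minimum summed abundance for a family to be kept.
#' @param scheme Size-class scheme for the modal class covariate.
#' @return A list of class `ppmr_community`: `abundance` (families x
#'   rectangles matrix) and `covariates` (tibble aligned with its rows).
#' @export
build_community_matrix <- function(matched, min_abundance = 5,
                                   scheme = size_class_scheme()) {
  x <- as_tibble(matched)
  if (!"prey_family" %in% names(x)) stop_ppmr("no prey_family column")
  x <- x[!is.na(x$prey_family) & !is.na(x$prey_count), ]
  if (!"ices_rectangle" %in% names(x)) {
    x$ices_rectangle <- ices_rectangle(x$lat, x$lon)
  }

  totals <- x |> count(.data$prey_family, wt = .data$prey_count, name = "total")
  drop <- totals$prey_family[totals$total < min_abundance]
  if (length(drop) > 0) {
    inform(sprintf("build_community_matrix: dropped %d famil%s below %d individuals",
                   length(drop), if (length(drop) == 1) "y" else "ies",
                   min_abundance))
    x <- x[!x$prey_family %in% drop, ]
  }
  if (nrow(x) == 0) stop_ppmr("no families left after abundance filtering")

  cells <- x |>
    group_by(.data$prey_family, .data$ices_rectangle) |>
    summarise(abundance = sum(.data$prey_count), .groups = "drop")
  mat <- cells |>
    tidyr::pivot_wider(names_from = "ices_rectangle",
                       values_from = "abundance", values_fill = 0)
  fam <- mat$prey_family
  mat <- as.matrix(mat[, -1, drop = FALSE])
  rownames(mat) <- fam

  covs <- x |>
    mutate(size_class = assign_size_class(.data$prey_indiv_mass_g, scheme)) |>
    group_by(.data$prey_family) |>
    summarise(
      mean_mass = sum(.data$prey_count * .data$prey_indiv_mass_g) /
        sum(.data$prey_count),
      mean_temp = sum(.data$prey_count * .data$sst_c) / sum(.data$prey_count),
      mean_effort = if ("effort_hours" %in% names(x)) {
        ok <- !is.na(.data$effort_hours)
        if (any(ok)) sum(.data$prey_count[ok] * .data$effort_hours[ok]) /
          sum(.data$prey_count[ok]) else NA_real_
      } else NA_real_,
      modal_size_class = names(which.max(
        tapply(.data$prey_count, .data$size_class, sum, default = 0))),
      total_abundance = sum(.data$prey_count),
      .groups = "drop"
    )
  covs <- covs[match(fam, covs$prey_family), ]

  structure(list(abundance = mat, covariates = covs),
            class = "ppmr_community")
}

#' Non-metric multidimensional scaling of the prey community
#'
#' Bray-Curtis dissimilarities among family rows, embedded in `k` dimensions
#' by iterative stress minimisation from multiple random starts (vegan's
#' engine); the best solution is centred and rotated to its principal axes
#' so coordinates are reproducible up to reflection. An optional fourth-root
#' abundance transform damps dominant families.
#'
#' @param community A `ppmr_community` (or a bare abundance matrix).
#' @param k Number of ordination dimensions.
#' @param seed Integer seed controlling the random starts.
#' @param starts Number of random starts.
#' @param transform `"none"` or `"fourthroot"`.
#' @return A list of class `ppmr_ordination`: `points` (rows = families),
#'   `stress` (Kruskal stress-1), `dist`, and the underlying vegan object.
#' @export
run_nmds <- function(community, k = 2, seed = 1, starts = 20,
                     transform = c("none", "fourthroot")) {
  transform <- match.arg(transform)
  mat <- if (inherits(community, "ppmr_community")) community$abundance
         else as.matrix(community)
  if (nrow(mat) < k + 2) stop_ppmr("need at least k + 2 rows for nMDS")
  if (transform == "fourthroot") mat <- mat^0.25
  d <- vegan::vegdist(mat, method = "bray")
  if (all(d == 0)) stop_ppmr("degenerate dissimilarity matrix: all zeros")
  set.seed(seed)
  ord <- vegan::metaMDS(d, k = k, try = starts, trymax = starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  pts <- vegan::scores(ord, display = "sites")
  rownames(pts) <- rownames(mat)
  structure(list(points = pts, stress = ord$stress, dist = d, engine = ord,
                 k = k, seed = seed, starts = starts),
            class = "ppmr_ordination")
}

#' @export
print.ppmr_ordination <- function(x, ...) {
  cat("<ppmr_ordination> k =", x$k, "| stress =", signif(x$stress, 4),
      "|", nrow(x$points), "points\n")
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each covariate, regresses it on the two ordination axes; the arrow is
#' the normalised coefficient direction, R-squared is that regression's
#' goodness of fit, and significance comes from permuting rows. Constant
#' covariates get R-squared 0 and are flagged.
#'
#' @param ordination A `ppmr_ordination` (or a 2-column coordinate matrix).
#' @param covariates Data frame of numeric covariates, rows aligned with the
#'   ordination points.
#' @param permutations Number of row permutations for the p-value.
#' @param seed Seed for the permutations.
#' @return A tibble with one row per covariate: `axis1`, `axis2` (unit
#'   arrow), `r2`, `p_value`, `constant` flag.
#' @export
fit_env_vectors <- function(ordination, covariates, permutations = 199,
                            seed = 1) {
  pts <- if (inherits(ordination, "ppmr_ordination")) ordination$points
         else as.matrix(ordination)
  covariates <- as.data.frame(covariates)
  covariates <- covariates[vapply(covariates, is.numeric, logical(1))]
  if (nrow(covariates) != nrow(pts)) {
    stop_ppmr("covariates must have one row per ordination point")
  }
  const <- vapply(covariates, function(v) sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  out <- vector("list", ncol(covariates))
  set.seed(seed)
  for (i in seq_along(covariates)) {
    nm <- names(covariates)[i]
    if (const[i]) {
      out[[i]] <- tibble(covariate = nm, axis1 = NA_real_, axis2 = NA_real_,
                         r2 = 0, p_value = NA_real_, constant = TRUE)
      next
    }
    ef <- vegan::envfit(pts, covariates[i], permutations = permutations,
                        na.rm = TRUE)
    arrow <- ef$vectors$arrows[1, ]
    out[[i]] <- tibble(covariate = nm, axis1 = unname(arrow[1]),
                       axis2 = unname(arrow[2]),
                       r2 = unname(ef$vectors$r[1]),
                       p_value = unname(ef$vectors$pvals[1]),
                       constant = FALSE)
  }
  bind_rows(out)
}
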