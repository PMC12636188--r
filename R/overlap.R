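# Overlap statistics between groups' foraging distributions: the home
# range overlap index (HROI) on core areas with its randomisation test,
# and Bhattacharyya's coefficient on utilisation distributions.

check_comparable <- function(a, b, force) {
  ma <- a$provenance$method %||% "unknown"
  mb <- b$provenance$method %||% "unknown"
  if (!force && !identical(ma, mb))
    stop("UDs estimated with different methods (", ma, " vs ", mb,
         ") are not directly comparable; pass force = TRUE to override")
}

#' Home range overlap index
#'
#' `HROI = (A_ij/A_i + A_ij/A_j) / 2`: the mean of the proportion of each
#' group's core foraging area intersected by the other's. Ranges from 0
#' (no overlap) to 1 (complete overlap). Areas are intersected cell-wise
#' on a common grid.
#'
#' @param region_i,region_j `ir_ud_region` objects on identical grids
#'   (conventionally 50% core areas).
#' @return Object of class `ir_overlap`: `A_i`, `A_j`, `A_ij` (km2),
#'   `hroi`.
#' @export
hroi <- function(region_i, region_j) {
  if (!grid_same(region_i$grid, region_j$grid))
    stop("hroi: regions are on different grids")
  if (region_i$area_km2 <= 0 || region_j$area_km2 <= 0)
    stop("hroi: zero-area region; index undefined")
  area <- grid_cell_area(region_i$grid)
  A_ij <- sum(region_i$cells & region_j$cells) * area
  structure(list(A_i = region_i$area_km2, A_j = region_j$area_km2,
                 A_ij = A_ij,
                 hroi = 0.5 * (A_ij / region_i$area_km2 +
                                 A_ij / region_j$area_km2)),
            class = "ir_overlap")
}

#' @export
print.ir_overlap <- function(x, ...) {
  cat(sprintf("<ir_overlap: HROI = %.3f (A_i %.0f, A_j %.0f, A_ij %.0f km2)%s>\n",
              x$hroi, x$A_i, x$A_j, x$A_ij,
              if (!is.null(x$p)) sprintf(", p = %.3f (%d perms)",
                                         x$p, x$n_perm) else ""))
  invisible(x)
}

# Mean of per-bird UD matrices for the given indices, as a region.
group_region <- function(ud_mats, idx, grid, level, method) {
  p <- Reduce(`+`, ud_mats[idx]) / length(idx)
  p <- p / sum(p)
  ud <- structure(list(grid = grid, p = p,
                       provenance = list(method = method)),
                  class = "ir_ud")
  ud_region(ud, level)
}

#' Randomisation test of core-area overlap
#'
#' Tests the null hypothesis that the core foraging areas of two groups
#' of birds do not differ, by shuffling bird identities across the groups
#' without replacement (preserving group sizes), recomputing group UDs,
#' core regions and HROI for each shuffle, and taking the p value as the
#' proportion of null HROI values strictly less than the observed value
#' (one-sided; p = 0 is possible). The bandwidth is held at its
#' observed-data value during permutations.
#'
#' @param uds_i,uds_j Lists of per-bird `ir_ud` on one common grid.
#' @param level Core-area level (default 0.5).
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @param plus_one If `TRUE`, apply the (B+1)/(N+1) correction instead of
#'   the strict proportion (off by default).
#' @param force Allow mixed-method comparisons.
#' @return `ir_overlap` with `p`, `n_perm`, `seed`, `null_hroi`.
#' @export
hroi_permutation_test <- function(uds_i, uds_j, level = 0.5,
                                  n_perm = 1000, seed = 1L,
                                  plus_one = FALSE, force = FALSE) {
  check_comparable(uds_i[[1]], uds_j[[1]], force)
  if (length(uds_i) < 2 || length(uds_j) < 2)
    warning("hroi_permutation_test: a group has < 2 birds; test is weak")
  g <- uds_i[[1]]$grid
  all_uds <- c(uds_i, uds_j)
  for (u in all_uds) if (!grid_same(u$grid, g))
    stop("hroi_permutation_test: UDs not on a common grid")
  mats <- lapply(all_uds, `[[`, "p")
  ni <- length(uds_i); n <- length(all_uds)
  method <- uds_i[[1]]$provenance$method
  obs <- hroi(group_region(mats, seq_len(ni), g, level, method),
              group_region(mats, (ni + 1):n, g, level, method))
  set.seed(seed)
  null_hroi <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, ni)
    r_i <- group_region(mats, idx, g, level, method)
    r_j <- group_region(mats, setdiff(seq_len(n), idx), g, level, method)
    hroi(r_i, r_j)$hroi
  }, numeric(1))
  obs$p <- if (plus_one) (sum(null_hroi < obs$hroi) + 1) / (n_perm + 1)
           else mean(null_hroi < obs$hroi)
  obs$n_perm <- n_perm
  obs$seed <- seed
  obs$null_hroi <- null_hroi
  obs
}

#' Bhattacharyya's coefficient between two utilisation distributions
#'
#' `BC = sum_x sqrt(UD_i(x) * UD_j(x))` over the cells of a common grid;
#' 0 for complete dissimilarity, 1 for identical distributions. Computed
#' without any small-sample bias correction ("uncorrected").
#'
#' @param ud_i,ud_j `ir_ud` objects on identical grids.
#' @param force Allow mixed-method comparisons.
#' @return Object of class `ir_bc`: `bc`, `correction = "uncorrected"`.
#' @export
bhattacharyya <- function(ud_i, ud_j, force = FALSE) {
  if (!grid_same(ud_i$grid, ud_j$grid))
    stop("bhattacharyya: UDs are on different grids")
  check_comparable(ud_i, ud_j, force)
  structure(list(bc = sum(sqrt(ud_i$p * ud_j$p)),
                 correction = "uncorrected"),
            class = "ir_bc")
}

#' @export
print.ir_bc <- function(x, ...) {
  cat(sprintf("<ir_bc: BC = %.4f (%s)>\n", x$bc, x$correction))
  invisible(x)
}
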