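#' Segment an MR volume into six tissue classes
#'
#' Gaussian-mixture segmentation fitted by expectation-maximisation.
#' The body outline is found by intensity thresholding and hole filling
#' (so internal air cavities stay inside the outline); voxels outside
#' it are air. The five tissue classes are fitted by EM on
#' supra-threshold body voxels, and a sixth air component — its
#' location and scale estimated robustly from outside-body intensities
#' — joins them in a final six-class E-step over all body voxels, so
#' dark-tissue tails are adjudicated against air by likelihood rather
#' than cut off at the threshold. Components are labelled by matching
#' their fitted mean ranks to the expected MR intensity ordering (or,
#' when `atlas_hint` is given, by majority overlap with the hinted
#' labels). A multiplicative bias field is re-estimated inside the EM
#' loop as a damped quadratic-polynomial fit to the class-centred
#' log-ratio of observed intensity and assigned class mean over
#' confidently classified voxels; on bias-free data the update is the
#' identity.
#'
#' @param mr MR [volume()] with non-negative intensities.
#' @param n_classes number of tissue classes (6).
#' @param atlas_hint optional [label_map()] used to name components by
#'   majority overlap instead of intensity ranks.
#' @param seed integer seed (initialisation is k-means based).
#' @param expected_order class names from darkest to brightest; default
#'   matches [mr_class_means()].
#' @param body optional BODY [binary_mask()]; derived by thresholding
#'   when NULL.
#' @param bias_correct estimate the multiplicative bias field.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `tissue_posteriors`: probability array
#'   (nx, ny, nz, 6), class names, grid.
#' @export
segment_tissues <- function(mr, n_classes = 6, atlas_hint = NULL,
                            seed = 1, expected_order = NULL,
                            body = NULL, bias_correct = TRUE,
                            max_iter = 300, tol = 1e-5) {
  stopifnot(n_classes == 6)
  withr::with_seed(seed, segment_tissues_impl(mr, atlas_hint,
                                              expected_order, body,
                                              bias_correct, max_iter, tol))
}

segment_tissues_impl <- function(mr, atlas_hint, expected_order, body,
                                 bias_correct, max_iter, tol) {
  g <- mr$grid
  classes <- names(tissue_classes())
  if (is.null(expected_order)) {
    expected_order <- names(sort(mr_class_means()))
  }
  x_raw <- as.numeric(mr$values)
  thr <- 0.10 * quantile(x_raw, 0.99)
  if (is.null(body)) {
    body <- binary_mask(fill_holes(array(x_raw > thr, g$shape)), g)
  }
  # air is claimed by thresholding everywhere (outside the body outline
  # and in internal cavities); the mixture fits the five tissue classes
  inside <- as.logical(body$member) & x_raw > thr
  x <- x_raw[inside]
  if (length(x) < 100) stop("body outline too small for segmentation")
  expected_order <- setdiff(expected_order, "air")

  K <- 5
  # initialisation: distinct values directly when the image is (near)
  # piecewise constant, k-means at intensity quantiles otherwise
  ux <- sort(unique(x))
  if (length(ux) <= K) {
    mu <- ux
  } else {
    centers <- unique(quantile(x, (seq_len(K) - 0.5) / K))
    km <- suppressWarnings(kmeans(x, centers = matrix(centers, ncol = 1),
                                  iter.max = 50))
    mu <- as.numeric(km$centers)
  }
  while (length(mu) < K) mu <- c(mu, max(mu) + diff(range(x)) / K + 1e-3)
  mu <- sort(mu)
  var_floor <- max((diff(range(x)) * 1e-4)^2, 1e-8)
  sg2 <- rep(max(stats::var(x) / K^2, var_floor), K)
  pk <- rep(1 / K, K)
  bias <- rep(1, length(x))
  xw <- x
  ll_old <- -Inf
  resp <- NULL
  converged <- FALSE
  coords <- NULL
  n_bias_updates <- 0L
  max_bias_updates <- 4L
  last_rel <- Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) {
      pk[k] * dnorm(xw, mu[k], sqrt(sg2[k]))
    }, numeric(length(xw)))
    rs <- rowSums(dens) + 1e-300
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    mu <- colSums(resp * xw) / pmax(nk, 1e-12)
    sg2 <- vapply(seq_len(K), function(k) {
      max(sum(resp[, k] * (xw - mu[k])^2) / max(nk[k], 1e-12), var_floor)
    }, numeric(1))
    pk <- pmax(nk / length(xw), 1e-12)
    pk <- pk / sum(pk)
    if (bias_correct && iter %% 5 == 0 &&
        n_bias_updates < max_bias_updates) {
      if (is.null(coords)) {
        ijk <- which(array(inside, g$shape), arr.ind = TRUE)
        coords <- sweep(sweep(ijk - 1, 2, g$spacing, "*"), 2, g$origin, "+")
        coords <- sweep(coords, 2, apply(abs(coords), 2, max), "/")
      }
      # the shading estimate must not absorb class structure: use only
      # confidently classified voxels, centre the log-ratio within each
      # class (removing class-mean and noise-scale offsets) and trim
      # outliers (mostly misclassified voxels) before the smooth fit
      hard <- max.col(resp)
      conf <- resp[cbind(seq_len(nrow(resp)), hard)] > 0.9 &
        x > 1e-3 * max(mu)
      if (sum(conf) > 500) {
        lr <- log(x[conf] / mu[hard[conf]])
        lr <- lr - ave(lr, hard[conf])
        keep <- abs(lr) <= 3 * stats::mad(lr) + 1e-12
        cf <- coords[conf, , drop = FALSE][keep, , drop = FALSE]
        lrk <- lr[keep]
        fit <- lm(lrk ~ cf[, 1] + cf[, 2] + cf[, 3] +
                    I(cf[, 1]^2) + I(cf[, 2]^2) + I(cf[, 3]^2) +
                    I(cf[, 1] * cf[, 2]) + I(cf[, 1] * cf[, 3]) +
                    I(cf[, 2] * cf[, 3]))
        b <- coef(fit)
        b[is.na(b)] <- 0
        cfa <- coords
        logb <- b[1] + cfa[, 1] * b[2] + cfa[, 2] * b[3] + cfa[, 3] * b[4] +
          cfa[, 1]^2 * b[5] + cfa[, 2]^2 * b[6] + cfa[, 3]^2 * b[7] +
          cfa[, 1] * cfa[, 2] * b[8] + cfa[, 1] * cfa[, 3] * b[9] +
          cfa[, 2] * cfa[, 3] * b[10]
        logb <- logb - mean(logb)
        # damped, clamped update: never trust a single fit fully, and
        # apply only substantial fields -- weak fits are dominated by
        # residual class structure rather than true shading
        logb <- 0.6 * pmin(pmax(logb, -0.3), 0.3)
        if (max(abs(logb)) > 0.02) {
          n_bias_updates <- n_bias_updates + 1L
          bias <- bias * exp(logb)
          xw <- x / bias
          ll_old <- -Inf  # objective changed; restart convergence window
          next
        }
      }
    }
    last_rel <- abs(ll - ll_old) / max(abs(ll_old), 1)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged && max_iter > 20) {
    stop(sprintf(paste0("EM did not converge in %d iterations ",
                        "(last log-likelihood %.6g, relative change %.3g, ",
                        "%d bias updates)"),
                 max_iter, ll, last_rel, n_bias_updates))
  }

  # name components: intensity ranks -> expected class order, or atlas
  ord <- order(mu)
  comp_class <- character(K)
  comp_class[ord] <- expected_order
  if (!is.null(atlas_hint)) {
    hint <- as.integer(atlas_hint$labels)[inside]
    cls <- tissue_classes()
    hard <- max.col(resp)
    for (k in seq_len(K)) {
      in_k <- hint[hard == k]
      if (length(in_k) > 0) {
        tab <- table(in_k)
        comp_class[k] <- names(cls)[cls == as.integer(names(tab)[
          which.max(tab)])]
      }
    }
    if (anyDuplicated(comp_class)) {  # fall back to rank labelling
      comp_class <- character(K)
      comp_class[ord] <- expected_order
    }
  }

  # final six-class E-step over all body voxels: the air component is
  # fitted from outside-body intensities (robust location/scale), so
  # sub-threshold tails of dark tissues (bone) are adjudicated against
  # air by likelihood rather than cut off at the outline threshold
  in_body <- as.logical(body$member)
  outside_vals <- x_raw[!in_body]
  mu_air <- if (length(outside_vals) > 0) median(outside_vals) else 0
  sd_air <- max(if (length(outside_vals) > 1) stats::mad(outside_vals)
                else 0, sqrt(var_floor))
  xb <- x_raw[in_body]
  # carry the estimated bias over to the EM domain; elsewhere it is 1
  xb_w <- xb
  xb_w[match(which(inside), which(in_body))] <- xw
  pk_air <- max(mean(xb <= thr), 1e-4)
  dens6 <- matrix(0, length(xb), 6)
  air_slot <- which(classes == "air")
  dens6[, air_slot] <- pk_air * dnorm(xb, mu_air, sd_air)
  for (k in seq_len(K)) {
    slot <- which(classes == comp_class[k])
    dens6[, slot] <- (1 - pk_air) * pk[k] * dnorm(xb_w, mu[k], sqrt(sg2[k]))
  }
  rs6 <- rowSums(dens6)
  if (any(rs6 == 0)) {
    # far-tail voxels whose densities underflowed in every component:
    # assign the nearest component mean deterministically
    zr <- which(rs6 == 0)
    mu_all <- c(mu_air, mu)
    cls_all <- c("air", comp_class)
    nearest <- cls_all[apply(abs(outer(xb_w[zr], mu_all, "-")), 1,
                             which.min)]
    dens6[cbind(zr, match(nearest, classes))] <- 1
    rs6[zr] <- 1
  }
  post <- array(0, c(g$shape, 6), dimnames = list(NULL, NULL, NULL, classes))
  flat <- matrix(0, length(x_raw), 6)
  flat[!in_body, air_slot] <- 1
  flat[in_body, ] <- dens6 / rs6
  post[] <- flat
  structure(list(prob = post, classes = classes, grid = g, body = body,
                 means = setNames(mu[match(classes, comp_class)], classes)),
            class = "tissue_posteriors")
}

# fill internal cavities: anything not reachable from the array border
# through non-member voxels becomes member
fill_holes <- function(member) {
  d <- dim(member)
  outside <- !member
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  lab <- .label_components_cpp(as.logical(outside), as.integer(d))
  dim(lab) <- d
  outer_labs <- unique(lab[border & outside])
  member | !(lab %in% outer_labs & outside)
}

#' Hard class masks from tissue posteriors
#'
#' Per-voxel argmax with ties broken by the fixed class priority
#' bone > CSF > GM > WM > soft > air. Connected components of bone or
#' air smaller than `min_component_cm3` are reassigned to soft tissue.
#' The returned masks are mutually exclusive and jointly exhaustive.
#'
#' @param post a `tissue_posteriors` object.
#' @param min_component_cm3 minimum kept component size for bone/air.
#' @return Named list of six [binary_mask()]s.
#' @export
masks_from_posteriors <- function(post, min_component_cm3 = 0.05) {
  g <- post$grid
  priority <- c("bone", "csf", "gm", "wm", "soft", "air")
  n <- prod(g$shape)
  best <- rep(-Inf, n)
  assign <- rep(NA_character_, n)
  for (cl in priority) {
    p <- as.numeric(post$prob[, , , cl])
    take <- p > best
    best[take] <- p[take]
    assign[take] <- cl
  }
  vox_cm3 <- voxel_volume_mm3(g) / 1000
  for (cl in c("bone", "air")) {
    m <- array(assign == cl, g$shape)
    if (!any(m)) next
    lab <- .label_components_cpp(as.logical(m), g$shape)
    sizes <- tabulate(lab)
    small <- which(sizes * vox_cm3 < min_component_cm3)
    if (length(small) > 0) {
      assign[lab %in% small] <- "soft"
    }
  }
  masks <- lapply(names(tissue_classes()), function(cl) {
    binary_mask(array(assign == cl, g$shape), g)
  })
  names(masks) <- names(tissue_classes())
  masks
}

#' Assemble the synthetic CT from class masks
#'
#' Piecewise-constant HU lookup over the six class masks.
#'
#' @param masks named list of six [binary_mask()]s partitioning the grid.
#' @param hu named HU lookup, see [hu_table()].
#' @return [volume()] with unit "HU".
#' @export
assemble_sct <- function(masks, hu = hu_table()) {
  cls <- names(tissue_classes())
  if (!all(cls %in% names(masks))) stop("masks must cover all six classes")
  g <- masks[[1]]$grid
  total <- Reduce(`+`, lapply(masks[cls], function(m) m$member))
  if (any(total != 1)) stop("masks must partition the grid exactly once")
  out <- array(0, g$shape)
  for (cl in cls) out[masks[[cl]]$member] <- hu[[cl]]
  volume(out, g, unit = "HU")
}

#' End-to-end sCT conversion
#'
#' Segment the MR, harden the posteriors into class masks, assemble the
#' HU image, and (if a different reference grid is given) resample the
#' class labels onto it with nearest-neighbour sampling before the HU
#' lookup, so the output stays piecewise constant in the six HU values.
#'
#' @param mr MR [volume()].
#' @param reference optional target [grid3d()] (default: the MR grid).
#' @param hu HU lookup table.
#' @param seed segmentation seed.
#' @param ... further arguments to [segment_tissues()].
#' @return sCT [volume()] (unit "HU").
#' @export
run_sct_pipeline <- function(mr, reference = NULL, hu = hu_table(),
                             seed = 1, ...) {
  post <- segment_tissues(mr, seed = seed, ...)
  masks <- masks_from_posteriors(post)
  if (is.null(reference) || grids_equal(mr$grid, reference)) {
    return(assemble_sct(masks, hu))
  }
  cls <- tissue_classes()
  lab <- array(0L, mr$grid$shape)
  for (cl in names(cls)) lab[masks[[cl]]$member] <- cls[[cl]]
  labv <- volume(array(as.numeric(lab), mr$grid$shape), mr$grid, "unitless")
  rl <- resample_to(labv, reference, mode = "nearest", fill = cls[["air"]])
  out <- array(unname(hu[names(cls)])[match(as.integer(round(rl$values)),
                                            cls)],
               reference$shape)
  volume(out, reference, unit = "HU")
}
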