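#' Segmentation parameters
#'
#' @param sigma Gaussian pre-smoothing of the membrane channel, in pixels.
#' @param seed_quantile seeds default to connected components of pixels below
#'   this intensity quantile of the smoothed membrane image (cell interiors
#'   are dark, membranes bright). Ignored when `seed_image` is given.
#' @param seed_image optional integer matrix of user-provided seed labels;
#'   overrides the automatic strategy.
#' @param min_area_px cells smaller than this are merged into the neighbor
#'   with the longest shared boundary (deterministic).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma = 1, seed_quantile = 0.5,
                                seed_image = NULL, min_area_px = 20) {
  stopifnot(sigma >= 0, min_area_px >= 1,
            seed_quantile > 0, seed_quantile < 1)
  structure(list(sigma = sigma, seed_quantile = seed_quantile,
                 seed_image = seed_image, min_area_px = min_area_px),
            class = "segmentation_params")
}

#' Seeded-watershed segmentation of one membrane-channel frame
#'
#' Smooths the membrane image, derives seed labels (automatically from
#' below-quantile connected components, or from `params$seed_image`), and
#' floods the intensity landscape from the seeds (EBImage's seeded region
#' growing). Small cells are merged deterministically. The resulting label
#' partition is skeletonized into cells, vertices and interfaces.
#'
#' @param image numeric matrix, single channel, finite values.
#' @param params a [segmentation_params].
#' @param meta an [imaging_metadata].
#' @param frame_index frame number stored in the result.
#' @return a [tissue_frame].
#' @export
segment_frame <- function(image, params = segmentation_params(),
                          meta = imaging_metadata(), frame_index = 1L) {
  if (!all(is.finite(image)))
    stop_invalid("image must be finite", "invalid_input")
  img <- image
  if (params$sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = params$sigma))
  if (is.null(params$seed_image)) {
    thr <- stats::quantile(img, params$seed_quantile)
    seeds_mask <- img < thr
    if (!any(seeds_mask))
      stop_invalid("no seeds found: image has no interior minima", "no_cells")
    seeds <- as.matrix(EBImage::bwlabel(seeds_mask))
    # drop speck seeds
    tab <- tabulate(seeds)
    small <- which(tab > 0 & tab < params$min_area_px / 4)
    if (length(small)) seeds[seeds %in% small] <- 0L
    if (!any(seeds > 0))
      stop_invalid("no seeds found: image has no interior minima", "no_cells")
  } else {
    seeds <- params$seed_image
  }
  lab <- as.matrix(EBImage::propagate(img, seeds = seeds))
  storage.mode(lab) <- "integer"
  lab <- merge_small_cells(lab, params$min_area_px)
  frame_from_labels(lab, meta = meta, frame_index = frame_index)
}

# Merge labels with area < min_area into the neighbor sharing the longest
# boundary; ties to the lower neighbor label. Iterates smallest-first.
merge_small_cells <- function(lab, min_area) {
  repeat {
    tab <- tabulate(lab, nbins = max(lab))
    small <- which(tab > 0 & tab < min_area)
    if (!length(small)) break
    target <- small[which.min(tab[small])]
    bl <- boundary_lengths(lab, target)
    if (!length(bl)) { lab[lab == target] <- 0L; next }
    best <- as.integer(names(bl)[bl == max(bl)])
    lab[lab == target] <- min(best)
  }
  # compact labels to 1..n
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[] <- match(lab, u, nomatch = 0L)
  storage.mode(lab) <- "integer"
  lab
}

# Named counts of 4-adjacent boundary contacts between `label` and each
# other positive label.
boundary_lengths <- function(lab, label) {
  nr <- nrow(lab); nc <- ncol(lab)
  touch <- integer(0)
  # vertical contacts
  a <- lab[-nr, , drop = FALSE]; b <- lab[-1, , drop = FALSE]
  sel <- (a == label & b != label & b > 0)
  touch <- c(touch, b[sel])
  sel <- (b == label & a != label & a > 0)
  touch <- c(touch, a[sel])
  # horizontal contacts
  a <- lab[, -nc, drop = FALSE]; b <- lab[, -1, drop = FALSE]
  sel <- (a == label & b != label & b > 0)
  touch <- c(touch, b[sel])
  sel <- (b == label & a != label & a > 0)
  touch <- c(touch, a[sel])
  if (!length(touch)) return(integer(0))
  table(touch)
}

#' Skeletonize a label image into cells, vertices and interfaces
#'
#' The label partition directly yields the tissue skeleton: boundary pixels
#' between exactly two labels form interface contours; 2x2 pixel blocks
#' containing three or more distinct labels (background included) are junction
#' candidates, clustered into one vertex per junction. Interface length is the
#' Euclidean vertex-vertex distance in micrometers; orientation is measured
#' from the AP image axis and folded to [0, 180).
#'
#' @param lab integer label matrix (0 = background allowed).
#' @param meta an [imaging_metadata].
#' @param frame_index stored frame number.
#' @return a [tissue_frame]. A one-cell image yields zero interfaces.
#' @export
frame_from_labels <- function(lab, meta = imaging_metadata(), frame_index = 1L) {
  storage.mode(lab) <- "integer"
  nr <- nrow(lab); nc <- ncol(lab)
  labels <- sort(unique(lab[lab > 0]))

  ## ---- vertices: 2x2 junction blocks on the 0-padded image ----
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  a <- pad[-nrow(pad), -ncol(pad)]; b <- pad[-1, -ncol(pad)]
  c2 <- pad[-nrow(pad), -1]; d <- pad[-1, -1]
  ndist <- n_distinct4(a, b, c2, d)
  cand <- which(ndist >= 3L, arr.ind = TRUE)
  vertices <- data.frame(vertex_id = integer(0), r = numeric(0), c = numeric(0))
  vert_labels <- list()
  if (nrow(cand)) {
    cm <- matrix(FALSE, nrow(a), ncol(a))
    cm[cand] <- TRUE
    comp <- as.matrix(EBImage::bwlabel(cm))
    ids <- sort(unique(comp[comp > 0]))
    vr <- vc <- numeric(length(ids))
    vert_labels <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      px <- which(comp == ids[k], arr.ind = TRUE)
      # block (i,j) on padded grid -> corner between original pixels:
      # position (i - 0.5, j - 0.5) in original 1-based pixel coordinates
      vr[k] <- mean(px[, 1]) - 0.5
      vc[k] <- mean(px[, 2]) - 0.5
      ls <- unique(c(a[px], b[px], c2[px], d[px]))
      vert_labels[[k]] <- ls
    }
    vertices <- data.frame(vertex_id = seq_along(ids), r = vr, c = vc)
  }

  ## ---- interface contour pixels: 4-adjacent unlike positive labels ----
  key <- function(x, y) {
    lo <- pmin(x, y); hi <- pmax(x, y)
    lo * (max(labels, 1L) + 1L) + hi
  }
  contour_px <- list(); pair_lo <- integer(0); pair_hi <- integer(0)
  collect <- function(i1, j1, i2, j2) {
    l1 <- lab[cbind(i1, j1)]; l2 <- lab[cbind(i2, j2)]
    sel <- l1 != l2 & l1 > 0L & l2 > 0L
    list(r = c(i1[sel], i2[sel]), c = c(j1[sel], j2[sel]),
         lo = rep(pmin(l1[sel], l2[sel]), 2L),
         hi = rep(pmax(l1[sel], l2[sel]), 2L))
  }
  iv <- expand.grid(i = seq_len(nr - 1L), j = seq_len(nc))
  vres <- collect(iv$i, iv$j, iv$i + 1L, iv$j)
  ih <- expand.grid(i = seq_len(nr), j = seq_len(nc - 1L))
  hres <- collect(ih$i, ih$j, ih$i, ih$j + 1L)
  br <- c(vres$r, hres$r); bc <- c(vres$c, hres$c)
  blo <- c(vres$lo, hres$lo); bhi <- c(vres$hi, hres$hi)

  interfaces <- data.frame(interface_id = character(0), cell_a = integer(0),
                           cell_b = integer(0), vertex_1 = integer(0),
                           vertex_2 = integer(0), length_px = numeric(0),
                           length_um = numeric(0), angle_deg = numeric(0),
                           class = character(0), stringsAsFactors = FALSE)
  contours <- list()
  if (length(br)) {
    pk <- paste(blo, bhi, sep = "|")
    groups <- split(seq_along(br), pk)
    n_int <- length(groups)
    ia <- ib <- v1 <- v2 <- integer(n_int)
    lpx <- ang <- numeric(n_int)
    contours <- vector("list", n_int)
    names_int <- names(groups)
    for (g in seq_len(n_int)) {
      idx <- groups[[g]]
      ab <- as.integer(strsplit(names_int[g], "|", fixed = TRUE)[[1]])
      px <- unique(cbind(br[idx], bc[idx]))
      # endpoints: incident vertices whose 2x2 block held both labels
      vin <- which(vapply(vert_labels, function(ls) all(ab %in% ls), logical(1)))
      if (length(vin) >= 2L) {
        if (length(vin) > 2L) {
          # the two mutually farthest incident vertices
          pos <- cbind(vertices$r[vin], vertices$c[vin])
          dd <- as.matrix(stats::dist(pos))
          w <- which(dd == max(dd), arr.ind = TRUE)[1, ]
          vin <- vin[w]
        }
        p1 <- c(vertices$r[vin[1]], vertices$c[vin[1]])
        p2 <- c(vertices$r[vin[2]], vertices$c[vin[2]])
        v1[g] <- vertices$vertex_id[vin[1]]; v2[g] <- vertices$vertex_id[vin[2]]
      } else {
        # border interface without two junctions: use contour extremes
        ctr <- colMeans(px)
        dev <- sweep(px, 2, ctr)
        dir <- svd(dev, nu = 0, nv = 1)$v[, 1]
        proj <- dev %*% dir
        p1 <- px[which.min(proj), ]; p2 <- px[which.max(proj), ]
        v1[g] <- NA_integer_; v2[g] <- NA_integer_
      }
      ia[g] <- ab[1]; ib[g] <- ab[2]
      lpx[g] <- sqrt(sum((p1 - p2)^2))
      ang[g] <- if (all(p1 == p2)) NA_real_ else
        interface_angle(p1, p2, meta)
      # order contour pixels along the chord
      dirv <- p2 - p1
      if (all(dirv == 0)) dirv <- c(0, 1)
      o <- order(as.numeric(sweep(px, 2, p1) %*% dirv))
      contours[[g]] <- px[o, , drop = FALSE]
    }
    interfaces <- data.frame(
      interface_id = paste(ia, ib, sep = "|"), cell_a = ia, cell_b = ib,
      vertex_1 = v1, vertex_2 = v2, length_px = lpx,
      length_um = lpx * meta$pixel_size, angle_deg = ang,
      class = "unclassified", stringsAsFactors = FALSE)
  }
  interfaces$contour <- contours

  ## ---- vertex incidence ----
  if (nrow(vertices)) {
    vertices$interfaces <- lapply(seq_len(nrow(vertices)), function(k) {
      ls <- vert_labels[[k]]
      which(interfaces$cell_a %in% ls & interfaces$cell_b %in% ls)
    })
  } else vertices$interfaces <- list()

  ## ---- cells ----
  cells <- data.frame(cell_id = labels)
  if (length(labels)) {
    idx <- which(lab > 0)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    ll <- lab[idx]
    area <- as.numeric(tapply(rep(1, length(ll)), ll, sum)[as.character(labels)])
    cr <- as.numeric(tapply(rr, ll, mean)[as.character(labels)])
    ccm <- as.numeric(tapply(cc, ll, mean)[as.character(labels)])
    nb <- lapply(labels, function(l)
      sort(unique(c(interfaces$cell_b[interfaces$cell_a == l],
                    interfaces$cell_a[interfaces$cell_b == l]))))
    border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    # labels 4-adjacent to background, in one pass
    a <- lab[-nr, , drop = FALSE]; b <- lab[-1, , drop = FALSE]
    bg_touch <- unique(c(a[b == 0L & a > 0L], b[a == 0L & b > 0L]))
    a <- lab[, -nc, drop = FALSE]; b <- lab[, -1, drop = FALSE]
    bg_touch <- unique(c(bg_touch, a[b == 0L & a > 0L], b[a == 0L & b > 0L]))
    tb <- labels %in% border_labels | labels %in% bg_touch
    per <- perimeter_px(lab, labels)
    cells <- data.frame(cell_id = labels, centroid_r = cr, centroid_c = ccm,
                        area_px = area, area_um2 = area * meta$pixel_size^2,
                        perimeter_um = per * meta$pixel_size,
                        touches_border = tb)
    cells$neighbors <- nb
  } else {
    cells <- data.frame(cell_id = integer(0), centroid_r = numeric(0),
                        centroid_c = numeric(0), area_px = numeric(0),
                        area_um2 = numeric(0), perimeter_um = numeric(0),
                        touches_border = logical(0))
    cells$neighbors <- list()
  }

  tissue_frame(frame_index, lab, cells, vertices, interfaces, meta)
}

# number of distinct values among four parallel matrices
n_distinct4 <- function(a, b, c2, d) {
  1L + (b != a) +
    ((c2 != a) & (c2 != b)) +
    ((d != a) & (d != b) & (d != c2))
}

# pixel-edge perimeter (count of exposed pixel edges) per label
perimeter_px <- function(lab, labels) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  exposed <- (core != pad[1:nr, 2:(nc + 1)]) +
    (core != pad[3:(nr + 2), 2:(nc + 1)]) +
    (core != pad[2:(nr + 1), 1:nc]) +
    (core != pad[2:(nr + 1), 3:(nc + 2)])
  out <- tapply(exposed[core > 0], core[core > 0], sum)
  as.numeric(out[as.character(labels)])
}
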