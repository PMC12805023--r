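#' Simulation configuration for synthetic kidney-like tissue
#'
#' Defines the ground-truth generative model: elliptical non-overlapping
#' nuclei with log-normal areas centred near 20 um^2 on a 2 um pixel grid
#' (about five 4 um^2 spots per nucleus), six cell types with multinomial
#' marker-driven expression, negative-binomial per-nucleus library sizes, a
#' Beta-distributed mitochondrial share, uniform ambient spill into a
#' dilation ring around each nucleus, and circular glomerulus-like niches in
#' which the three glomerular types (podocyte-like, endothelial-like,
#' mesangial-like) are interleaved.
#'
#' @param canvas_px integer `(rows, cols)` canvas size in pixels.
#' @param pitch_um pixel (= spot) size in micrometres.
#' @param n_nuclei number of nuclei to place.
#' @param mean_area_um2 mean nuclear area (um^2) of the log-normal area law.
#' @param area_cv coefficient of variation of nuclear area.
#' @param type_props named cell-type proportions (must sum to 1). Names
#'   containing the glomerular types (see `glomerular_types`) are confined to
#'   glomerulus disks; all others are placed outside them.
#' @param glomerular_types character; types restricted to glomeruli.
#' @param n_glomeruli,glomerulus_radius_um number and radius of the circular
#'   glomerulus-like regions.
#' @param n_genes total panel size (markers + mitochondrial + housekeeping).
#' @param n_markers_per_type markers per cell type.
#' @param marker_fold_change expression fold-change of a marker in its own
#'   type over every other type.
#' @param n_mito_genes number of mitochondrial (`MT-`) genes.
#' @param library_mean,library_size negative-binomial mean and size of the
#'   per-nucleus transcript count.
#' @param area_coupling exponent coupling the expected library size to
#'   relative nuclear area (`mu_i = library_mean * (area_i /
#'   mean_area)^area_coupling`); 0.5 yields the moderate positive
#'   counts-area association seen in nucleus-binned data (R^2 ~ 0.2).
#' @param mito_mean,mito_conc mean and concentration of the Beta law for the
#'   per-nucleus mitochondrial fraction.
#' @param ambient_fraction probability that a transcript is displaced out of
#'   its nucleus into the surrounding ring (cytoplasmic/ambient spill).
#' @param ambient_dilation_px radius (pixels) of the spill ring.
#' @param batch_effect standard deviation of the log-normal per-gene batch
#'   factors used by [generate_cohort()].
#' @param seed integer seed.
#' @return A `sim_config` (named list).
#' @export
sim_config <- function(canvas_px = c(256L, 256L),
                       pitch_um = 2,
                       n_nuclei = 1000L,
                       mean_area_um2 = 20,
                       area_cv = 0.35,
                       type_props = c(
                         podocyte = 0.06,
                         glom_endothelial = 0.07,
                         mesangial = 0.07,
                         proximal_tubule = 0.40,
                         distal_tubule = 0.25,
                         immune = 0.15
                       ),
                       glomerular_types = c("podocyte", "glom_endothelial",
                                            "mesangial"),
                       n_glomeruli = 4L,
                       glomerulus_radius_um = 44,
                       n_genes = 500L,
                       n_markers_per_type = 10L,
                       marker_fold_change = 8,
                       n_mito_genes = 10L,
                       library_mean = 120,
                       library_size = 8,
                       area_coupling = 0.5,
                       mito_mean = 0.025,
                       mito_conc = 60,
                       ambient_fraction = 0.1,
                       ambient_dilation_px = 3L,
                       batch_effect = 0,
                       seed = 1L) {
  if (abs(sum(type_props) - 1) > 1e-8) {
    abort("type_props must sum to 1", class = "nucbin_validation_error")
  }
  if (n_nuclei < length(type_props)) {
    abort("n_nuclei must be at least the number of cell types",
          class = "nucbin_validation_error")
  }
  n_marker_genes <- n_markers_per_type * length(type_props)
  if (n_genes < n_marker_genes + n_mito_genes) {
    abort("n_genes too small for the requested markers and mito genes",
          class = "nucbin_validation_error")
  }
  if (ambient_fraction < 0 || ambient_fraction >= 1) {
    abort("ambient_fraction must lie in [0, 1)", class = "nucbin_validation_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

# gene panel: canonical kidney markers first within each type block, then
# synthetic filler markers, MT- genes, and housekeeping genes
build_gene_panel <- function(config) {
  canonical <- list(
    podocyte = c("NPHS2", "PODXL"),
    glom_endothelial = c("PECAM1", "PLVAP", "EHD3", "CLIC4"),
    mesangial = c("PDGFRB"),
    proximal_tubule = c("GPX3", "DPEP1", "ANPEP")
  )
  types <- names(config$type_props)
  k <- config$n_markers_per_type
  markers <- lapply(types, function(t) {
    base <- canonical[[t]] %||% character()
    base <- head(base, k)
    extra <- if (length(base) < k) {
      sprintf("%s-M%02d", toupper(substr(t, 1, 4)), seq_len(k - length(base)))
    } else character()
    c(base, extra)
  })
  names(markers) <- types
  mito <- sprintf("MT-G%02d", seq_len(config$n_mito_genes))
  n_hk <- config$n_genes - length(unlist(markers)) - length(mito)
  hk <- sprintf("HK%03d", seq_len(n_hk))
  list(
    gene_ids = c(unlist(markers, use.names = FALSE), mito, hk),
    markers = markers,
    mito = mito
  )
}

# relative expression rates (genes x types) over non-mito genes
build_profiles <- function(config, panel) {
  types <- names(config$type_props)
  non_mito <- setdiff(panel$gene_ids, panel$mito)
  prof <- matrix(1, nrow = length(non_mito), ncol = length(types),
                 dimnames = list(non_mito, types))
  for (t in types) prof[panel$markers[[t]], t] <- config$marker_fold_change
  prof
}

# pixels (1-based linear indices) covered by an ellipse; pixel centers on
# integer coordinates (0-based)
ellipse_pixels <- function(cy, cx, a_px, b_px, theta, nr, nc) {
  r0 <- max(0L, floor(cy - a_px)); r1 <- min(nr - 1L, ceiling(cy + a_px))
  c0 <- max(0L, floor(cx - a_px)); c1 <- min(nc - 1L, ceiling(cx + a_px))
  if (r0 > r1 || c0 > c1) return(integer())
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(r = rr, c = cc)
  dy <- g$r - cy; dx <- g$c - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  inside <- u * u + v * v <= 1
  (g$r[inside] + 1L) + g$c[inside] * nr
}

disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d <- d[d$dr^2 + d$dc^2 <= radius^2, ]
  d
}

# ring of pixels within `radius` of the set `px`, excluding `px`; clipped to
# the canvas
dilation_ring <- function(px, radius, nr, nc) {
  if (radius <= 0L || !length(px)) return(integer())
  offs <- disk_offsets(radius)
  r <- (px - 1L) %% nr
  c <- (px - 1L) %/% nr
  rr <- rep(r, each = nrow(offs)) + offs$dr
  cc <- rep(c, each = nrow(offs)) + offs$dc
  ok <- rr >= 0L & rr < nr & cc >= 0L & cc < nc
  cand <- unique((rr[ok] + 1L) + cc[ok] * nr)
  setdiff(cand, px)
}

#' Generate one synthetic tissue
#'
#' Draws the ground truth (nucleus geometry, cell types, per-nucleus library
#' sizes and mitochondrial fractions), allocates transcripts to genes by the
#' cell-type profiles, places each transcript on the spot grid — inside its
#' nucleus with probability `1 - ambient_fraction`, otherwise uniformly in a
#' dilation ring around it — and returns both the observed [spot_grid()] and
#' the truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param gene_factors optional positive multiplier per non-mito gene applied
#'   to all expression profiles (used for batch effects).
#' @param zero_genes optional gene identifiers whose expression is set to 0
#'   (transcript-degradation artifact).
#' @param batch_id identifier stored in the truth (default 1).
#' @return List with elements `spots` (a `spot_grid` covering the whole
#'   canvas) and `truth` (a `tissue_truth`: nucleus table, label image,
#'   profiles, marker map, glomerulus table, config, seed).
#' @export
generate_tissue <- function(config, seed = config$seed, gene_factors = NULL,
                            zero_genes = NULL, batch_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nr <- as.integer(config$canvas_px[1]); nc <- as.integer(config$canvas_px[2])
  pitch <- config$pitch_um
  n <- as.integer(config$n_nuclei)
  types <- names(config$type_props)

  panel <- build_gene_panel(config)
  prof <- build_profiles(config, panel)
  if (!is.null(gene_factors)) prof <- prof * gene_factors
  if (!is.null(zero_genes)) prof[rownames(prof) %in% zero_genes, ] <- 0
  if (any(colSums(prof) <= 0)) {
    abort("degenerate expression profile (all rates zero for a type)",
          class = "nucbin_validation_error")
  }

  # glomerulus-like disks, non-overlapping, away from the border
  g_rad <- config$glomerulus_radius_um / pitch
  glom <- place_glomeruli(config$n_glomeruli, g_rad, nr, nc)

  cell_type <- sample(types, n, replace = TRUE, prob = config$type_props)
  in_glom <- cell_type %in% config$glomerular_types

  sdlog <- sqrt(log(1 + config$area_cv^2))
  meanlog <- log(config$mean_area_um2) - sdlog^2 / 2
  areas <- rlnorm(n, meanlog, sdlog)

  occupied <- matrix(0L, nr, nc)
  pixel_sets <- vector("list", n)
  centroid <- matrix(NA_real_, n, 2)
  # place constrained (glomerular) nuclei first so crowding in small disks
  # does not depend on draw order
  for (i in order(!in_glom)) {
    a_um <- sqrt(areas[i] * runif(1, 1.1, 1.6) / pi)
    b_um <- areas[i] / (pi * a_um)
    a_px <- max(a_um, b_um) / pitch
    b_px <- min(a_um, b_um) / pitch
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      if (in_glom[i]) {
        gi <- sample.int(nrow(glom), 1L)
        ang <- runif(1, 0, 2 * pi)
        # glomerular micro-anatomy: podocytes line the tuft periphery while
        # endothelial and mesangial nuclei occupy the core, so the types are
        # radially zoned (with an overlap band) rather than fully interleaved
        rng <- if (cell_type[i] == "podocyte") c(0.6, 1) else c(0, 0.75)
        rad <- sqrt(runif(1, rng[1]^2, rng[2]^2)) * (g_rad - a_px - 1)
        cy <- glom$row[gi] + rad * sin(ang); cx <- glom$col[gi] + rad * cos(ang)
      } else {
        cy <- runif(1, 0, nr - 1); cx <- runif(1, 0, nc - 1)
        if (nrow(glom) &&
            any((cy - glom$row)^2 + (cx - glom$col)^2 < (g_rad + a_px)^2)) next
      }
      theta <- runif(1, 0, pi)
      px <- ellipse_pixels(cy, cx, a_px, b_px, theta, nr, nc)
      if (!length(px)) {
        cand <- (round(min(max(cy, 0), nr - 1)) + 1L) +
          round(min(max(cx, 0), nc - 1)) * nr
        px <- cand
      }
      if (all(occupied[px] == 0L)) {
        occupied[px] <- i
        pixel_sets[[i]] <- px
        centroid[i, ] <- c(mean((px - 1L) %% nr), mean((px - 1L) %/% nr))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0("could not place nucleus ", i,
                   " without overlap; enlarge the canvas or reduce n_nuclei"),
            class = "nucbin_placement_error")
    }
  }

  n_px <- lengths(pixel_sets)

  mu_i <- config$library_mean *
    (n_px * pitch^2 / config$mean_area_um2)^config$area_coupling
  lib <- pmax(1L, rnbinom(n, mu = mu_i, size = config$library_size))
  mito_frac <- rbeta(n, config$mito_mean * config$mito_conc,
                     (1 - config$mito_mean) * config$mito_conc)
  mito_counts <- rbinom(n, lib, mito_frac)
  nonmito_counts <- lib - mito_counts

  n_genes <- config$n_genes
  gene_index <- setNames(seq_len(n_genes), panel$gene_ids)
  mito_idx <- gene_index[panel$mito]
  nonmito_idx <- gene_index[rownames(prof)]

  ring_cache <- lapply(pixel_sets, dilation_ring,
                       radius = config$ambient_dilation_px, nr = nr, nc = nc)

  ii <- vector("list", n); jj <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prof[, cell_type[i]]
    g_non <- if (nonmito_counts[i] > 0) {
      drop(rmultinom(1, nonmito_counts[i], p))
    } else numeric(length(nonmito_idx))
    g_mito <- if (mito_counts[i] > 0) {
      drop(rmultinom(1, mito_counts[i], rep(1, length(mito_idx))))
    } else numeric(length(mito_idx))
    genes_i <- c(rep(nonmito_idx, g_non), rep(mito_idx, g_mito))
    li <- length(genes_i)
    n_amb <- rbinom(1, li, config$ambient_fraction)
    px_i <- integer(li)
    own <- pixel_sets[[i]]
    ring <- ring_cache[[i]]
    if (!length(ring)) ring <- own
    amb <- rep(FALSE, li)
    if (n_amb > 0) amb[sample.int(li, n_amb)] <- TRUE
    px_i[!amb] <- own[sample.int(length(own), sum(!amb), replace = TRUE)]
    if (n_amb > 0) px_i[amb] <- ring[sample.int(length(ring), n_amb, replace = TRUE)]
    ii[[i]] <- px_i
    jj[[i]] <- genes_i
  }
  counts <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                         dims = c(nr * nc, n_genes),
                         dimnames = list(NULL, panel$gene_ids))

  spot_idx <- seq_len(nr * nc)
  spots <- spot_grid(counts,
                     spot_row = (spot_idx - 1L) %% nr,
                     spot_col = (spot_idx - 1L) %/% nr,
                     gene_ids = panel$gene_ids, pitch_um = pitch,
                     mito_flags = panel$gene_ids %in% panel$mito)

  truth <- structure(list(
    nuclei = tibble(
      nucleus_id = seq_len(n),
      cell_type = cell_type,
      centroid_row = centroid[, 1],
      centroid_col = centroid[, 2],
      n_px = n_px,
      area_um2 = n_px * pitch^2,
      library_size = as.integer(lib),
      mito_frac = mito_frac,
      in_glomerulus = in_glom
    ),
    label_image = label_image(occupied, pixel_size_um = pitch),
    profiles = prof,
    markers = panel$markers,
    mito_genes = panel$mito,
    glomeruli = glom,
    ambient_fraction = config$ambient_fraction,
    batch_id = batch_id,
    config = config,
    seed = seed
  ), class = "tissue_truth")

  list(spots = spots, truth = truth)
}

place_glomeruli <- function(n_glom, g_rad, nr, nc, max_attempts = 2000L) {
  if (n_glom < 1L) return(tibble(glomerulus_id = integer(), row = numeric(),
                                 col = numeric(), radius_px = numeric()))
  rows <- numeric(0); cols <- numeric(0)
  for (g in seq_len(n_glom)) {
    for (attempt in seq_len(max_attempts)) {
      cy <- runif(1, g_rad, nr - 1 - g_rad)
      cx <- runif(1, g_rad, nc - 1 - g_rad)
      if (!length(rows) || all((cy - rows)^2 + (cx - cols)^2 >= (2.2 * g_rad)^2)) {
        rows <- c(rows, cy); cols <- c(cols, cx)
        break
      }
      if (attempt == max_attempts) {
        abort("could not place glomeruli without overlap; enlarge the canvas",
              class = "nucbin_placement_error")
      }
    }
  }
  tibble(glomerulus_id = seq_len(n_glom), row = rows, col = cols,
         radius_px = g_rad)
}

#' @export
print.tissue_truth <- function(x, ...) {
  cat(sprintf("<tissue_truth> %d nuclei, %d gene profiles, batch %s\n",
              nrow(x$nuclei), nrow(x$profiles), format(x$batch_id)))
  invisible(x)
}
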