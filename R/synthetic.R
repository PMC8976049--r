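#' Specification for a synthetic spatial transcriptomics dataset
#'
#' Describes a simulated tissue: a spot lattice (hexagonal Visium-like,
#' square grid, or uniform-random Slide-seq-like), contiguous spatial
#' domains (stacked layers, concentric rings, or a cord-plus-arrow shape
#' over background), and a negative-binomial expression model in which
#' each domain up-regulates its own block of marker genes. Library sizes
#' vary log-uniformly per spot; multi-section mode replicates the
#' geometry per section and adds per-section multiplicative batch shifts
#' to the gene means.
#'
#' Defaults describe the standard validation tissue used throughout the
#' package: a 1000-spot hexagonal lattice with three layers, 200 genes,
#' 50 markers per domain at a 2 log2 fold-change, and NB dispersion 0.5
#' (UMI-like overdispersion).
#'
#' @param lattice `"hex"`, `"grid"`, or `"uniform"`.
#' @param n_spots spots per section.
#' @param domain_geometry `"layers"`, `"concentric"`, or `"cord-arrow"`
#'   (the latter fixes three domains: background, cord, arrow).
#' @param n_domains number of spatial domains.
#' @param n_genes total genes.
#' @param n_markers_per_domain genes up-regulated in each domain
#'   (disjoint blocks).
#' @param effect_size marker log2 fold-change inside the domain.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_range per-spot library scaling factors, sampled
#'   log-uniformly in this range.
#' @param n_sections number of consecutive sections (1 = 2D).
#' @param batch_shift_sd sd of the per-section log-normal gene-mean
#'   shift (multi-section only).
#' @param seed RNG seed; generation is bit-reproducible for a fixed spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(lattice = "hex", n_spots = 1000,
                           domain_geometry = "layers", n_domains = 3,
                           n_genes = 200, n_markers_per_domain = 50,
                           effect_size = 2, nb_dispersion = 0.5,
                           library_size_range = c(0.5, 2),
                           n_sections = 1, batch_shift_sd = 0.5,
                           seed = 0) {
  lattice <- match.arg(lattice, c("hex", "grid", "uniform"))
  domain_geometry <- match.arg(domain_geometry,
                               c("layers", "concentric", "cord-arrow"))
  if (domain_geometry == "cord-arrow") n_domains <- 3L
  stopifnot(n_domains >= 1, n_spots >= n_domains, n_genes >= 1,
            n_markers_per_domain >= 0,
            n_domains * n_markers_per_domain <= n_genes,
            nb_dispersion >= 0, n_sections >= 1,
            length(library_size_range) == 2,
            all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2])
  structure(list(lattice = lattice, n_spots = n_spots,
                 domain_geometry = domain_geometry,
                 n_domains = as.integer(n_domains), n_genes = n_genes,
                 n_markers_per_domain = n_markers_per_domain,
                 effect_size = effect_size, nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 n_sections = as.integer(n_sections),
                 batch_shift_sd = batch_shift_sd, seed = seed),
            class = "synthetic_spec")
}

make_lattice <- function(lattice, n) {
  if (lattice == "hex") {
    nx <- ceiling(sqrt(n / (sqrt(3) / 2)))
    ny <- ceiling(n / nx)
    row <- rep(seq_len(ny), each = nx)[seq_len(n)]
    col <- rep(seq_len(nx), times = ny)[seq_len(n)]
    cbind(x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
  } else if (lattice == "grid") {
    nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
    row <- rep(seq_len(ny), each = nx)[seq_len(n)]
    col <- rep(seq_len(nx), times = ny)[seq_len(n)]
    cbind(x = as.numeric(col), y = as.numeric(row))
  } else {
    side <- sqrt(n)
    cbind(x = stats::runif(n, 0, side), y = stats::runif(n, 0, side))
  }
}

assign_domains <- function(coords, geometry, k) {
  x <- coords[, 1]; y <- coords[, 2]
  if (geometry == "layers") {
    br <- seq(min(y), max(y), length.out = k + 1)
    br[1] <- br[1] - 1e-9; br[k + 1] <- br[k + 1] + 1e-9
    as.integer(cut(y, breaks = br))
  } else if (geometry == "concentric") {
    d <- sqrt((x - mean(range(x)))^2 + (y - mean(range(y)))^2)
    br <- stats::quantile(d, probs = seq(0, 1, length.out = k + 1))
    br[1] <- br[1] - 1e-9; br[k + 1] <- br[k + 1] + 1e-9
    as.integer(cut(d, breaks = br))
  } else {  # cord-arrow: background 1, cord arc 2, arrow V 3
    rx <- diff(range(x)); ry <- diff(range(y))
    cx <- mean(range(x)); cy <- mean(range(y))
    scale <- min(rx, ry)
    d <- sqrt((x - cx)^2 + (y - (cy + 0.15 * ry))^2)
    ang <- atan2(y - (cy + 0.15 * ry), x - cx)
    cord <- abs(d - 0.3 * scale) < 0.07 * scale & ang < -pi * 0.1 &
      ang > -pi * 0.9
    vy <- (cy + 0.1 * ry) + 0.6 * abs(x - cx)
    arrow <- abs(y - vy) < 0.07 * scale & abs(x - cx) < 0.35 * rx
    lab <- rep(1L, length(x))
    lab[arrow] <- 3L
    lab[cord] <- 2L
    lab
  }
}

#' Generate a synthetic spatial transcriptomics dataset
#'
#' Realizes a [synthetic_spec()]: places spots, assigns contiguous
#' domains, and samples negative-binomial counts in which each domain's
#' marker block has its mean multiplied by `2^effect_size`. Ground-truth
#' labels and marker indices are returned alongside the dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `raw` ([raw_dataset()]), `labels` (integer domain
#'   per spot, constant across sections), `marker_genes` (list of gene
#'   index vectors per domain), and `spec`.
#' @export
generate_spatial_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  coords1 <- make_lattice(spec$lattice, spec$n_spots)
  labels1 <- assign_domains(coords1, spec$domain_geometry, spec$n_domains)
  ns <- spec$n_sections
  coords <- do.call(rbind, replicate(ns, coords1, simplify = FALSE))
  labels <- rep(labels1, ns)
  section <- if (ns > 1) rep(seq_len(ns), each = spec$n_spots) else NULL
  n <- nrow(coords); G <- spec$n_genes
  base_mu <- exp(stats::rnorm(G, mean = log(2), sd = 0.5))
  markers <- lapply(seq_len(spec$n_domains), function(d)
    if (spec$n_markers_per_domain == 0) integer(0) else
      ((d - 1) * spec$n_markers_per_domain + 1):(d * spec$n_markers_per_domain))
  fc <- 2^spec$effect_size
  mu <- matrix(base_mu, n, G, byrow = TRUE)
  for (d in seq_len(spec$n_domains)) {
    rows <- which(labels == d)
    if (length(markers[[d]]) > 0)
      mu[rows, markers[[d]]] <- mu[rows, markers[[d]]] * fc
  }
  if (ns > 1 && spec$batch_shift_sd > 0) {
    for (s in seq_len(ns)) {
      shift <- exp(stats::rnorm(G, 0, spec$batch_shift_sd))
      rows <- which(section == s)
      mu[rows, ] <- sweep(mu[rows, , drop = FALSE], 2, shift, "*")
    }
  }
  lib <- exp(stats::runif(n, log(spec$library_size_range[1]),
                          log(spec$library_size_range[2])))
  mu <- mu * lib
  size <- if (spec$nb_dispersion > 0) 1 / spec$nb_dispersion else Inf
  counts <- if (is.finite(size)) {
    matrix(stats::rnbinom(n * G, mu = mu, size = size), n, G)
  } else {
    matrix(stats::rpois(n * G, lambda = mu), n, G)
  }
  spot_ids <- if (ns > 1) {
    paste0("s", section, "_spot", rep(seq_len(spec$n_spots), ns))
  } else paste0("spot", seq_len(n))
  rownames(counts) <- spot_ids
  colnames(counts) <- paste0("gene", seq_len(G))
  raw <- raw_dataset(counts, coords, section = section)
  list(raw = raw, labels = labels, marker_genes = markers, spec = spec)
}

#' Corrupt a dataset with dropout
#'
#' Simulates capture inefficiency: with `mode = "zero"` each nonzero
#' count is independently set to zero with probability `rate`; with
#' `mode = "thin"` each count is binomially downsampled, keeping each
#' molecule with probability `1 - rate`. Totals never increase.
#'
#' @param raw a [raw_dataset()].
#' @param rate dropout probability in `[0, 1)`.
#' @param mode `"zero"` or `"thin"`.
#' @param seed RNG seed.
#' @return a corrupted `raw_dataset`.
#' @export
corrupt_dropout <- function(raw, rate, mode = c("zero", "thin"), seed = 0) {
  stopifnot(inherits(raw, "raw_dataset"), rate >= 0, rate < 1)
  mode <- match.arg(mode)
  if (rate == 0) return(raw)
  set.seed(seed)
  counts <- raw$counts
  nz <- counts@x
  if (mode == "zero") {
    drop <- stats::runif(length(nz)) < rate
    counts@x[drop] <- 0
  } else {
    counts@x <- as.double(stats::rbinom(length(nz), size = round(nz),
                                        prob = 1 - rate))
  }
  counts <- Matrix::drop0(counts)
  raw_dataset(counts, raw$coords, gene_names = raw$gene_names,
              spot_ids = raw$spot_ids, in_tissue = raw$in_tissue,
              section = raw$section)
}
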