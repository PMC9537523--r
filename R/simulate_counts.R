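# Negative-binomial UMI count generator with planted structure: group
# markers, high-dispersion genes, a latent cell-cycle program loading both
# known and novel genes, ribosomal/mitochondrial decoys, and QC outlier
# cells. The planted gene sets are returned as ground truth for validating
# the HVG, cell-cycle-removal, and marker-ranking procedures.

#' Simulate a UMI count matrix with known structure
#'
#' The matrix emulates the informative slice of a droplet transcriptome:
#' per-gene baseline means are log-normal, counts are negative binomial
#' with mild overdispersion, and per-cell library sizes vary log-normally.
#' Planted structure:
#' \describe{
#'   \item{markers}{`markers_per_group` genes per group with mean fold
#'     change `marker_fc` in their group.}
#'   \item{HVGs}{`n_hvg` genes with strongly inflated dispersion
#'     (negative-binomial size `hvg_size`), independent of group and cell
#'     cycle.}
#'   \item{cell cycle}{a latent per-cell cycle score multiplies the means
#'     of `n_cc` genes drawn from the known cell-cycle list plus
#'     `n_cc_extra` novel genes (names `CCX*`), producing the mutual
#'     Spearman correlations the two-step removal looks for.}
#'   \item{housekeeping}{`n_housekeeping` highly expressed, near-ubiquitous
#'     genes that carry most of the library depth, as ribosomal and
#'     metabolic genes do in real droplet data; they exercise the
#'     detection-fraction and mean-expression candidacy bounds.}
#'   \item{decoys}{a handful of moderately dispersed `RPL*`/`RPS*`/`MT-*`
#'     genes exercising the prefix-removal rules.}
#'   \item{outliers}{`n_outliers` cells whose counts are concentrated in a
#'     small fraction of genes (high UMIs, few genes), off the
#'     genes-vs-UMIs trend.}
#' }
#'
#' @param n_genes,n_cells Matrix dimensions (defaults 2000 x 600).
#' @param n_groups Number of cell groups.
#' @param markers_per_group,marker_fc Planted marker count and fold change.
#' @param n_hvg,hvg_size Planted high-dispersion gene count and their NB
#'   size (smaller = more dispersed).
#' @param n_cc,n_cc_extra Known and novel cell-cycle-program genes.
#' @param cc_beta Log-scale loading of the latent cycle score.
#' @param n_outliers Planted QC outlier cells.
#' @param n_housekeeping High-expression genes setting the library depth.
#' @param base_size NB size of background genes.
#' @param seed Integer seed (mandatory).
#' @return List with `counts` (genes x cells integer matrix), `truth`
#'   (planted gene sets, group labels, outlier barcodes), and `groups`
#'   (label per cell).
#' @export
simulate_counts <- function(n_genes = 2000, n_cells = 600, n_groups = 3,
                            markers_per_group = 50, marker_fc = 4,
                            n_hvg = 100, hvg_size = 0.15,
                            n_cc = 40, n_cc_extra = 20, cc_beta = 1.2,
                            n_outliers = 0, n_housekeeping = 60,
                            base_size = 8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_decoy <- 8L
  n_planted <- n_groups * markers_per_group + n_hvg + n_cc + n_cc_extra +
    n_decoy + n_housekeeping
  if (n_planted >= n_genes) stop("n_genes too small for the planted sets")
  set.seed(seed)

  marker_genes <- lapply(seq_len(n_groups), function(g) {
    sprintf("MKG%d_%02d", g, seq_len(markers_per_group))
  })
  names(marker_genes) <- paste0("group", seq_len(n_groups))
  hvg_genes <- sprintf("HVG%03d", seq_len(n_hvg))
  cc_known <- utils::head(default_cell_cycle_genes(), n_cc)
  cc_extra <- sprintf("CCX%02d", seq_len(n_cc_extra))
  decoys <- c("RPL3", "RPL13A", "RPS6", "RPS18", "MT-CO1", "MT-ND1",
              "MT-CYB", "MTRNR2L1")
  housekeeping <- sprintf("HK%02d", seq_len(n_housekeeping))
  n_bg <- n_genes - n_planted
  bg <- sprintf("G%04d", seq_len(n_bg))
  genes <- c(unlist(marker_genes, use.names = FALSE), hvg_genes, cc_known,
             cc_extra, decoys, housekeeping, bg)

  mu <- stats::rlnorm(n_genes, meanlog = log(0.08), sdlog = 1.1)
  mu <- pmin(mu, 2)
  names(mu) <- genes
  mu[unlist(marker_genes)] <- stats::runif(n_groups * markers_per_group,
                                           0.1, 0.4)
  mu[hvg_genes] <- stats::runif(n_hvg, 0.15, 0.7)
  mu[c(cc_known, cc_extra)] <- stats::runif(n_cc + n_cc_extra, 0.3, 0.9)
  mu[decoys] <- stats::runif(n_decoy, 0.3, 0.8)
  mu[housekeeping] <- stats::runif(n_housekeeping, 20, 80)

  size <- rep(base_size, n_genes)
  names(size) <- genes
  size[hvg_genes] <- hvg_size
  size[decoys] <- 0.5
  size[housekeeping] <- 20

  groups <- sample(paste0("group", seq_len(n_groups)), n_cells,
                   replace = TRUE)
  sf <- stats::rlnorm(n_cells, 0, 0.3)
  cc_score <- stats::rnorm(n_cells)

  barcodes <- sprintf("cell-%04d", seq_len(n_cells))
  counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, barcodes))
  cc_all <- c(cc_known, cc_extra)
  for (j in seq_len(n_cells)) {
    mu_j <- mu * sf[j]
    mk <- marker_genes[[groups[j]]]
    mu_j[mk] <- mu_j[mk] * marker_fc
    mu_j[cc_all] <- mu_j[cc_all] * exp(cc_beta * cc_score[j])
    counts[, j] <- stats::rnbinom(n_genes, mu = mu_j, size = size)
  }

  outlier_barcodes <- character(0)
  if (n_outliers > 0) {
    out_idx <- sample(n_cells, n_outliers)
    outlier_barcodes <- barcodes[out_idx]
    for (j in out_idx) {
      few <- sample(n_genes, round(0.05 * n_genes))
      x <- integer(n_genes)
      x[few] <- stats::rnbinom(length(few), mu = mu[few] * sf[j] * 25,
                               size = base_size)
      counts[, j] <- x
    }
  }

  list(counts = counts,
       truth = list(markers = marker_genes, hvg_genes = hvg_genes,
                    cc_known = cc_known, cc_extra = cc_extra,
                    decoys = decoys, outlier_barcodes = outlier_barcodes,
                    cc_score = cc_score),
       groups = groups)
}
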