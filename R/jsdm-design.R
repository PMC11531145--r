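#' Prepare jSDM inputs from root and soil communities
#'
#' Builds the binary response and the candidate design-matrix blocks for the
#' joint species distribution model:
#' \describe{
#'   \item{P}{host-plant dummy columns (treatment coding against the most
#'     frequent genus);}
#'   \item{S}{principal coordinates of the Bray-Curtis dissimilarities
#'     between soil communities, retained to `cum_threshold` cumulative
#'     contribution, mapped to root samples by sampling position;}
#'   \item{Sp}{spatial eigenvectors of the sampling positions, mapped to
#'     root samples by position.}
#' }
#' Root samples whose position lacks a soil sample are dropped, as are root
#' samples of infrequent host plants (fewer than `min_host_samples`
#' samples). OTUs that are absent from (or present in) every retained sample
#' carry no occurrence information for a probit model and are dropped with a
#' message.
#'
#' @param root_table Root community matrix (counts or binary).
#' @param soil_table Soil community matrix (one sample per position).
#' @param metadata Sample metadata covering both tables.
#' @param min_host_samples Host plants with fewer root samples are excluded
#'   (strict `<`; default 30, use 15 for the reduced-design variant).
#' @param cum_threshold Cumulative-contribution cutoff for soil PCoA axes.
#' @param max_s_axes,max_sp_vectors Optional caps on the soil-axis and
#'   spatial-eigenvector block widths.
#' @param extra_covariates Optional data frame of additional continuous
#'   covariates (e.g. soil pH) keyed by `position_id`.
#' @return An object of class `jsdm_design`: list with the binary response
#'   `Y`, blocks `X_P`, `X_S`, `X_Sp`, `X_extra`, and the retained metadata.
#' @export
prepare_inputs <- function(root_table, soil_table, metadata,
                           min_host_samples = 30, cum_threshold = 0.90,
                           max_s_axes = Inf, max_sp_vectors = Inf,
                           extra_covariates = NULL) {
  md <- validate_metadata(metadata)
  root_table <- validate_community(root_table)
  soil_table <- validate_community(soil_table)
  root_md <- md[md$kind == "root" & md$sample_id %in% rownames(root_table), ]
  soil_md <- md[md$kind == "soil" & md$sample_id %in% rownames(soil_table), ]

  # positions require soil data
  keep_pos <- soil_md$position_id
  dropped_pos <- setdiff(unique(root_md$position_id), keep_pos)
  if (length(dropped_pos) > 0)
    message("dropping root samples at ", length(dropped_pos),
            " position(s) without soil data")
  root_md <- root_md[root_md$position_id %in% keep_pos, ]

  # infrequent hosts out (strict <)
  host_n <- table(root_md$host_plant)
  keep_hosts <- names(host_n)[host_n >= min_host_samples]
  if (length(keep_hosts) < 2)
    stop("fewer than two host-plant levels remain after filtering")
  root_md <- root_md[root_md$host_plant %in% keep_hosts, ]

  if (!is.null(extra_covariates)) {
    extra_covariates <- tibble::as_tibble(extra_covariates)
    stopifnot("position_id" %in% names(extra_covariates))
    miss <- setdiff(root_md$position_id, extra_covariates$position_id)
    if (length(miss) > 0) {
      message("dropping root samples at ", length(miss),
              " position(s) without extra covariate data")
      root_md <- root_md[!root_md$position_id %in% miss, ]
    }
  }

  Y <- to_binary(root_table[root_md$sample_id, , drop = FALSE])
  occ <- colSums(Y)
  keep_otus <- occ >= 1 & occ <= nrow(Y) - 1
  if (!all(keep_otus))
    message("dropping ", sum(!keep_otus), " OTU(s) with no occurrence variation")
  Y <- Y[, keep_otus, drop = FALSE]
  if (ncol(Y) == 0) stop("no OTUs left to model")

  # P block
  host <- factor(root_md$host_plant,
                 levels = names(sort(host_n[keep_hosts], decreasing = TRUE)))
  X_P <- stats::model.matrix(~host)[, -1, drop = FALSE]
  colnames(X_P) <- paste0("P_", levels(host)[-1])

  # S block: soil PCoA axes by position
  soil_sub <- soil_table[soil_md$sample_id, , drop = FALSE]
  ord <- pcoa_axes(bray_curtis(soil_sub), cum_threshold = cum_threshold,
                   max_axes = max_s_axes)
  soil_axes <- ord$coordinates
  rownames(soil_axes) <- soil_md$position_id
  X_S <- soil_axes[root_md$position_id, , drop = FALSE]
  colnames(X_S) <- paste0("S_", seq_len(ncol(X_S)))

  # Sp block: spatial eigenvectors of the retained positions
  sev <- spatial_eigenvectors(soil_md[soil_md$position_id %in% root_md$position_id, ],
                              n_vectors = max_sp_vectors)
  X_Sp <- sev$vectors[root_md$position_id, , drop = FALSE]
  colnames(X_Sp) <- paste0("Sp_", seq_len(ncol(X_Sp)))

  X_extra <- NULL
  if (!is.null(extra_covariates)) {
    ec_cols <- setdiff(names(extra_covariates), "position_id")
    X_extra <- as.matrix(extra_covariates[match(root_md$position_id,
                                                extra_covariates$position_id),
                                          ec_cols, drop = FALSE])
    colnames(X_extra) <- paste0("E_", ec_cols)
  }

  scale01 <- function(m) {
    if (is.null(m) || ncol(m) == 0) return(m)
    s <- apply(m, 2, stats::sd)
    if (any(s == 0)) stop("constant non-intercept design column")
    scale(m)[, , drop = FALSE]
  }
  X_S <- scale01(X_S); X_Sp <- scale01(X_Sp); X_extra <- scale01(X_extra)
  rownames(X_P) <- rownames(X_S) <- rownames(X_Sp) <- root_md$sample_id
  if (!is.null(X_extra)) rownames(X_extra) <- root_md$sample_id

  structure(list(Y = Y, X_P = X_P, X_S = X_S, X_Sp = X_Sp, X_extra = X_extra,
                 metadata = root_md, soil_ordination = ord,
                 spatial = sev, otu_ids = colnames(Y)),
            class = "jsdm_design")
}

#' @export
print.jsdm_design <- function(x, ...) {
  cat(sprintf("jSDM design: %d root samples x %d OTUs; blocks P=%d, S=%d, Sp=%d%s\n",
              nrow(x$Y), ncol(x$Y), ncol(x$X_P), ncol(x$X_S), ncol(x$X_Sp),
              if (is.null(x$X_extra)) "" else sprintf(", extra=%d", ncol(x$X_extra))))
  invisible(x)
}

# Assemble the model matrix for a factor-inclusion spec (intercept always in).
assemble_design <- function(design, include) {
  X <- matrix(1, nrow(design$Y), 1, dimnames = list(rownames(design$Y), "(Intercept)"))
  if (include[["P"]]) X <- cbind(X, design$X_P)
  if (include[["S"]]) X <- cbind(X, design$X_S)
  if (include[["Sp"]]) X <- cbind(X, design$X_Sp)
  if (!is.null(design$X_extra) && isTRUE(include[["extra"]]))
    X <- cbind(X, design$X_extra)
  X
}

#' The 16-model factor lattice
#'
#' All combinations of the four candidate factors: host plant (P), soil
#' community structure (S), spatial autocorrelation (Sp) and fungus-fungus
#' covariance (Cov). Model 1 is the full model and model 16 the
#' intercept-only null.
#'
#' @return A tibble with columns `model`, `name`, `P`, `S`, `Sp`, `Cov`.
#' @export
model_lattice <- function() {
  spec <- tibble::tribble(
    ~model, ~name,                      ~P,    ~S,    ~Sp,   ~Cov,
    1L, "Full (P + S + Sp + Cov)",      TRUE,  TRUE,  TRUE,  TRUE,
    2L, "P + S + Sp",                   TRUE,  TRUE,  TRUE,  FALSE,
    3L, "P + S + Cov",                  TRUE,  TRUE,  FALSE, TRUE,
    4L, "P + Sp + Cov",                 TRUE,  FALSE, TRUE,  TRUE,
    5L, "S + Sp + Cov",                 FALSE, TRUE,  TRUE,  TRUE,
    6L, "P + S",                        TRUE,  TRUE,  FALSE, FALSE,
    7L, "P + Sp",                       TRUE,  FALSE, TRUE,  FALSE,
    8L, "P + Cov",                      TRUE,  FALSE, FALSE, TRUE,
    9L, "S + Sp",                       FALSE, TRUE,  TRUE,  FALSE,
    10L, "S + Cov",                     FALSE, TRUE,  FALSE, TRUE,
    11L, "Sp + Cov",                    FALSE, FALSE, TRUE,  TRUE,
    12L, "P",                           TRUE,  FALSE, FALSE, FALSE,
    13L, "S",                           FALSE, TRUE,  FALSE, FALSE,
    14L, "Sp",                          FALSE, FALSE, TRUE,  FALSE,
    15L, "Cov",                         FALSE, FALSE, FALSE, TRUE,
    16L, "Null",                        FALSE, FALSE, FALSE, FALSE)
  spec
}
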