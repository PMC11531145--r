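#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a jSDM fit into a long coefficient table
#'
#' @param x A `jsdm_fit`.
#' @param ... Unused.
#' @return A tibble with `otu_id`, `term`, `estimate`.
#' @method tidy jsdm_fit
#' @export
tidy.jsdm_fit <- function(x, ...) {
  B <- x$B
  out <- tibble::tibble(
    otu_id = rep(colnames(B), each = nrow(B)),
    term = rep(rownames(B), ncol(B)),
    estimate = as.vector(B))
  if (!is.null(x$Lambda)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      otu_id = rep(rownames(x$Lambda), ncol(x$Lambda)),
      term = rep(colnames(x$Lambda), each = nrow(x$Lambda)),
      estimate = as.vector(x$Lambda)))
  }
  out
}

#' One-row summary of a jSDM fit
#'
#' @param x A `jsdm_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `log_lik`, `auc`, `r`, `n_otus`,
#'   `n_samples`, `converged`.
#' @method glance jsdm_fit
#' @export
glance.jsdm_fit <- function(x, ...) {
  tibble::tibble(model = x$name, log_lik = x$ll_total, auc = roc_auc(x),
                 r = x$r, n_otus = ncol(x$Y), n_samples = nrow(x$Y),
                 converged = x$converged)
}

#' Tidy a model lattice into its log-likelihood table
#'
#' @param x A `jsdm_lattice`.
#' @param ... Unused.
#' @return A tibble sorted by decreasing log-likelihood.
#' @method tidy jsdm_lattice
#' @export
tidy.jsdm_lattice <- function(x, ...) {
  out <- tibble::as_tibble(x[, c("model", "name", "P", "S", "Sp", "Cov",
                                 "ll", "auc")])
  out[order(-out$ll), ]
}

#' Tidy factor attribution into the per-OTU LLR table
#'
#' @param x A `factor_attribution`.
#' @param ... Unused.
#' @return The per-OTU tibble (`otu_id`, `factor`, `llr`, and `guild` when
#'   available).
#' @method tidy factor_attribution
#' @export
tidy.factor_attribution <- function(x, ...) x$llr

#' Tidy an SLR fit into its edge list
#'
#' @param x An `slr_fit`.
#' @param ... Unused.
#' @return A tibble: `otu1`, `otu2`, `partial_cor`, `sign`.
#' @method tidy slr_fit
#' @export
tidy.slr_fit <- function(x, ...) {
  net <- extract_network(x)
  out <- net$edges[, c("otu1", "otu2", "weight", "sign")]
  names(out)[3] <- "partial_cor"
  out
}

#' One-row summary of an SLR fit
#'
#' @param x An `slr_fit`.
#' @param ... Unused.
#' @return A tibble with `rank`, `n_edges`, `lambda`, `gamma`, `bic`,
#'   `eigmin`, `converged`.
#' @method glance slr_fit
#' @export
glance.slr_fit <- function(x, ...) {
  tibble::tibble(rank = x$rank, n_edges = x$n_edges, lambda = x$lambda,
                 gamma = x$gamma, bic = x$bic, eigmin = x$eigmin,
                 converged = x$converged)
}

#' Tidy a preference result into the OTU-level table
#'
#' @param x A `preference_result`.
#' @param ... Unused.
#' @return The per-OTU tibble.
#' @method tidy preference_result
#' @export
tidy.preference_result <- function(x, ...) x$otu

#' Tidy a Steel-Dwass result into the pairwise table
#'
#' @param x A `steel_dwass` object.
#' @param ... Unused.
#' @return The pairwise tibble.
#' @method tidy steel_dwass
#' @export
tidy.steel_dwass <- function(x, ...) x$pairs
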