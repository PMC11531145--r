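#' Root-versus-soil habitat surface
#'
#' For every OTU passing the occurrence filters, the number of root and soil
#' samples in which it occurs and its mean relative abundance (log10 of the
#' read proportion, averaged over the samples where present, with half the
#' smallest positive proportion as the offset inside the log) in each
#' habitat.
#'
#' @param root_table,soil_table Community matrices.
#' @param metadata Sample metadata.
#' @param min_root Minimum root-sample occurrences (default 30).
#' @param min_soil Minimum soil-sample occurrences (default 15).
#' @return A tibble of class `habitat_points`, one row per retained OTU.
#' @export
habitat_surface <- function(root_table, soil_table, metadata,
                            min_root = 30, min_soil = 15) {
  root_table <- validate_community(root_table)
  soil_table <- validate_community(soil_table)
  common <- intersect(colnames(root_table), colnames(soil_table))
  occ_r <- colSums(root_table[, common, drop = FALSE] > 0)
  occ_s <- colSums(soil_table[, common, drop = FALSE] > 0)
  keep <- common[occ_r >= min_root & occ_s >= min_soil]
  if (length(keep) == 0) stop("no OTUs pass the habitat occurrence filters")
  mean_logprop <- function(tab, otus) {
    prop <- tab / rowSums(tab)
    eps <- min(prop[prop > 0]) / 2
    vapply(otus, function(o) {
      v <- prop[tab[, o] > 0, o]
      mean(log10(v + eps))
    }, numeric(1), USE.NAMES = FALSE)
  }
  out <- tibble::tibble(
    otu_id = keep,
    n_root_detected = as.integer(occ_r[keep]),
    n_soil_detected = as.integer(occ_s[keep]),
    mean_log_rel_abund_root = mean_logprop(root_table, keep),
    mean_log_rel_abund_soil = mean_logprop(soil_table, keep))
  class(out) <- c("habitat_points", class(out))
  out
}

#' Poisson GLM of root occurrence on soil relative abundance
#'
#' For each OTU, the number of root samples containing the OTU is counted
#' per (position, host genus) cell and modelled as Poisson with a log link;
#' predictors are the log-transformed soil relative abundance of the OTU at
#' the position and host-genus identity, with the log of the cell's total
#' root-sample count as an offset. The soil coefficient is standardised by
#' the predictor's standard deviation; its Wald p-value is reported.
#'
#' @param root_table,soil_table Community matrices.
#' @param metadata Sample metadata.
#' @param otus OTUs to fit (default: those passing [habitat_surface()]
#'   filters).
#' @param min_root,min_soil Occurrence filters used when `otus` is `NULL`.
#' @return A tibble of class `glm_soil_coupling`: `otu_id`,
#'   `soil_coefficient` (standardised), `p_value`, `converged`.
#' @export
glm_soil_coupling <- function(root_table, soil_table, metadata, otus = NULL,
                              min_root = 30, min_soil = 15) {
  md <- validate_metadata(metadata)
  root_table <- validate_community(root_table)
  soil_table <- validate_community(soil_table)
  if (is.null(otus))
    otus <- habitat_surface(root_table, soil_table, metadata,
                            min_root, min_soil)$otu_id
  root_md <- md[md$kind == "root" & md$sample_id %in% rownames(root_table), ]
  soil_md <- md[md$kind == "soil" & md$sample_id %in% rownames(soil_table), ]
  root_md <- root_md[root_md$position_id %in% soil_md$position_id, ]
  cells <- dplyr::count(root_md, .data$position_id, .data$host_plant,
                        name = "exposure")
  soil_prop <- soil_table / rowSums(soil_table)
  eps <- min(soil_prop[soil_prop > 0]) / 2
  rownames(soil_prop) <- soil_md$position_id[match(rownames(soil_table),
                                                   soil_md$sample_id)]
  pres <- root_table > 0
  res <- lapply(otus, function(o) {
    cnt <- tapply(pres[root_md$sample_id, o],
                  list(root_md$position_id, root_md$host_plant), sum)
    y <- cnt[cbind(cells$position_id, cells$host_plant)]
    sab <- log10(soil_prop[cells$position_id, o] + eps)
    dat <- data.frame(y = as.integer(y), soil = sab,
                      host = factor(cells$host_plant),
                      exposure = cells$exposure)
    form <- if (nlevels(dat$host) > 1)
      y ~ soil + host + offset(log(exposure))
    else y ~ soil + offset(log(exposure))
    fit <- suppressWarnings(
      stats::glm(form, family = stats::poisson(), data = dat))
    sm <- summary(fit)$coefficients
    if (!"soil" %in% rownames(sm) || stats::sd(sab) == 0)
      return(tibble::tibble(otu_id = o, soil_coefficient = 0,
                            p_value = NA_real_, converged = fit$converged))
    tibble::tibble(otu_id = o,
                   soil_coefficient = unname(sm["soil", 1]) * stats::sd(sab),
                   p_value = unname(sm["soil", 4]),
                   converged = fit$converged)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("glm_soil_coupling", class(out))
  out
}
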