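#' Read an array manifest (id, chrom, pos)
#' @param path tab-delimited file with header columns `id`, `chrom`, `pos`.
#' @return data.frame of variants.
#' @export
read_manifest <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("id", "chrom", "pos") %in% names(dt)))
  data.frame(id = as.character(dt$id), chrom = as.character(dt$chrom),
             pos = as.integer(dt$pos), stringsAsFactors = FALSE)
}

#' Read a GWAS-hit catalog (id, p_value, optional phenotype)
#' @param path tab-delimited file with header.
#' @return data.frame.
#' @export
read_catalog <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = "p_value"))
  stopifnot(all(c("id", "p_value") %in% names(dt)))
  as.data.frame(dt)
}

#' Read an LD table into a proxy map
#'
#' Accepts the package's own `id_a, id_b, r2` header as well as
#' PLINK/VCFtools-style `.ld` headers (`SNP_A, SNP_B, R2`, case-insensitive,
#' extra columns ignored, whitespace-delimited).
#'
#' @param path file path.
#' @param r2_threshold minimum retained r2 (default 0.8).
#' @return a [proxy_map()].
#' @export
read_ld_table <- function(path, r2_threshold = 0.8) {
  dt <- data.table::fread(path, header = TRUE)
  nm <- tolower(names(dt))
  pick <- function(alts) {
    i <- which(nm %in% alts)[1]
    if (is.na(i)) stopf("LD table lacks a column among: %s",
                        paste(alts, collapse = ", "))
    dt[[i]]
  }
  proxy_map(data.frame(id_a = as.character(pick(c("id_a", "snp_a"))),
                       id_b = as.character(pick(c("id_b", "snp_b"))),
                       r2 = as.numeric(pick(c("r2", "r^2"))),
                       stringsAsFactors = FALSE),
            r2_threshold = r2_threshold)
}

#' Read GWAS summary statistics (id, beta, se, p)
#' @param path tab-delimited file with header; `se` or `p` may be absent
#'   (but not both).
#' @return data.frame.
#' @export
read_sumstats <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot("id" %in% names(dt), "beta" %in% names(dt),
            any(c("se", "p") %in% names(dt)))
  as.data.frame(dt)
}

#' Write / read an annotation matrix as TSV
#'
#' The matrix goes to `<path>` (first column `id`, then one column per
#' feature); feature metadata (mode, clump group) goes to
#' `<path>.features.tsv`.
#'
#' @param am an [annotation_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_matrix <- function(am, path) {
  dt <- data.table::data.table(id = rownames(am$values))
  for (j in seq_len(ncol(am$values))) dt[[am$features$name[j]]] <- am$values[, j]
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(am$features, paste0(path, ".features.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_annotation_matrix
#' @export
read_annotation_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  f_path <- paste0(path, ".features.tsv")
  vals <- as.matrix(dt[, -1])
  rownames(vals) <- as.character(dt$id)
  feats <- if (file.exists(f_path)) {
    f <- data.table::fread(f_path, header = TRUE, sep = "\t")
    feature_defs(f$name, f$mode,
                 ifelse(is.na(f$clump_group) | f$clump_group == "",
                        NA_character_, as.character(f$clump_group)))
  } else NULL
  annotation_matrix(vals, feats)
}

#' Write / read hit labels as TSV (id, label)
#' @param labels a [hit_labeling()] (LD-excluded ids are not serialized).
#' @param path output TSV path.
#' @return `path` invisibly; `read_labels` returns a `hit_labeling`.
#' @export
write_labels <- function(labels, path) {
  dt <- data.table::data.table(
    id = c(labels$hit_ids, labels$nonhit_ids),
    label = c(rep(1L, length(labels$hit_ids)),
              rep(0L, length(labels$nonhit_ids))))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_labels
#' @param tier,phenotype metadata restored onto the read labeling.
#' @export
read_labels <- function(path, tier = "weak", phenotype = "all") {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("id", "label") %in% names(dt)))
  hit_labeling(as.character(dt$id), as.character(dt$id)[dt$label == 1],
               tier = tier, phenotype = phenotype)
}

#' Write prediction scores as TSV (id, score)
#' @param scores named numeric vector.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  data.table::fwrite(data.table::data.table(id = names(scores),
                                            score = unname(scores)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stats::setNames(dt$score, as.character(dt$id))
}

#' Serialize / restore a fitted model
#'
#' Coefficients as TSV (`feature, coefficient`) plus a JSON sidecar with the
#' intercept, hyperparameters, weights and options.
#'
#' @param fit a [fit_elastic_net()] result.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly; `read_model` returns a `fit_result`.
#' @export
write_model <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(
    data.table::data.table(feature = names(fit$coefficients),
                           coefficient = unname(fit$coefficients)),
    file.path(dir, "coefficients.tsv"), sep = "\t")
  meta <- list(intercept = fit$intercept, alpha = fit$alpha,
               lambda = fit$lambda, standardize = fit$standardize,
               thresh = fit$thresh,
               w_hit = fit$weights$w_hit, w_nonhit = fit$weights$w_nonhit,
               n_hits = fit$weights$n_hits, n_nonhits = fit$weights$n_nonhits,
               constant_features = as.list(fit$constant_features))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  cf <- data.table::fread(file.path(dir, "coefficients.tsv"),
                          header = TRUE, sep = "\t")
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  structure(list(intercept = meta$intercept,
                 coefficients = stats::setNames(cf$coefficient,
                                                as.character(cf$feature)),
                 alpha = meta$alpha, lambda = meta$lambda,
                 weights = compute_class_weights(meta$n_hits, meta$n_nonhits),
                 standardize = meta$standardize, thresh = meta$thresh,
                 constant_features = unlist(meta$constant_features)),
            class = "fit_result")
}
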