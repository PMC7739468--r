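#' Ortholog-group by species regulation matrix
#'
#' The gene-centered summary of the reconstruction: one row per ortholog
#' group, one column per species, cells holding the posterior probability of
#' regulation of the member gene's operon (NA where the species lacks an
#' ortholog — absence is a distinct category, not probability zero). Rows
#' are sorted by decreasing average posterior over present members, ties
#' broken by group id.
#'
#' @param groups list of `ortholog_group` objects carrying a `posteriors`
#'   element (named numeric per species).
#' @param species_order character vector fixing the column order.
#' @return A `regulon_matrix`: numeric matrix (rows named by group id) with
#'   attribute `avg_posterior`.
#' @export
build_regulon_matrix <- function(groups, species_order) {
  if (length(groups) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(species_order),
                dimnames = list(NULL, species_order))
    return(structure(m, avg_posterior = numeric(0),
                     class = c("regulon_matrix", "matrix", "array")))
  }
  m <- t(vapply(groups, function(g) {
    row <- setNames(rep(NA_real_, length(species_order)), species_order)
    p <- g$posteriors
    row[intersect(names(p), species_order)] <-
      p[intersect(names(p), species_order)]
    row
  }, numeric(length(species_order))))
  rownames(m) <- vapply(groups, `[[`, character(1), "group_id")
  avg <- apply(m, 1, function(r) mean(r, na.rm = TRUE))
  ord <- order(-avg, rownames(m))
  m <- m[ord, , drop = FALSE]
  structure(m, avg_posterior = avg[ord],
            class = c("regulon_matrix", "matrix", "array"))
}

#' @export
print.regulon_matrix <- function(x, ...) {
  cat(sprintf("Regulon matrix: %d ortholog groups x %d species\n",
              nrow(x), ncol(x)))
  if (nrow(x)) {
    print(round(head(cbind(unclass(x),
                           avg = attr(x, "avg_posterior")), 10), 3))
    if (nrow(x) > 10) cat("...\n")
  }
  invisible(x)
}

#' Write all analysis reports
#'
#' Writes the per-species site and operon CSVs, the ortholog-group matrix
#' CSV, the mixture-motif PFMs, the per-group ancestral CSVs and an
#' annotated tree, plus a manifest listing every file with its MD5 checksum.
#' Figures (heatmap, tree) are only drawn when `figures = TRUE` so the
#' pipeline runs headless by default.
#'
#' @param result a `regulon_reconstruction` object.
#' @param out_dir output directory (created if needed).
#' @param figures draw PNG figures as well.
#' @return data.frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.csv`.
#' @export
write_reports <- function(result, out_dir, figures = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  for (sp in names(result$species)) {
    res <- result$species[[sp]]
    emit(res$sites, sprintf("sites_%s.csv", sp))
    emit(res$operon_table, sprintf("operons_%s.csv", sp))
    mp <- file.path(out_dir, sprintf("motif_%s.pfm", sp))
    write_pfm(result$motifs[[sp]]$pswm, mp, id = sp)
    written <- c(written, mp)
  }
  # ortholog group matrix
  m <- result$matrix
  if (nrow(m)) {
    df <- data.frame(group_id = rownames(m),
                     avg_posterior = attr(m, "avg_posterior"),
                     unclass(m)[, , drop = FALSE], check.names = FALSE)
    members <- do.call(rbind, lapply(result$groups, function(g) {
      data.frame(group_id = g$group_id,
                 t(setNames(g$members[colnames(m)], colnames(m))),
                 check.names = FALSE)
    }))
    names(members)[-1] <- paste0("locus_", colnames(m))
    df <- merge(df, members, by = "group_id", sort = FALSE)
  } else {
    df <- data.frame(group_id = character(0), avg_posterior = numeric(0))
  }
  emit(df, "ortholog_groups.csv")
  # ancestral reports
  if (length(result$ancestral)) {
    anc <- do.call(rbind, lapply(names(result$ancestral), function(gid) {
      np <- result$ancestral[[gid]]$node_probs
      data.frame(group_id = gid, node = rownames(np),
                 p_s0 = np[, "s0"], p_s1 = np[, "s1"], p_sa = np[, "sa"],
                 row.names = NULL)
    }))
    emit(anc, "ancestral_states.csv")
  } else {
    emit(data.frame(group_id = character(0), node = character(0),
                    p_s0 = numeric(0), p_s1 = numeric(0),
                    p_sa = numeric(0)), "ancestral_states.csv")
  }
  if (!is.null(result$tree)) {
    tp <- file.path(out_dir, "tf_tree.nwk")
    ape::write.tree(result$tree, file = tp)
    written <- c(written, tp)
  }
  if (figures && nrow(result$matrix)) {
    fp <- file.path(out_dir, "regulon_heatmap.png")
    grDevices::png(fp, width = 900, height = 200 + 24 * nrow(result$matrix))
    plot(result)
    grDevices::dev.off()
    written <- c(written, fp)
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  if (nrow(result$matrix) == 0L) {
    manifest <- rbind(manifest,
                      data.frame(file = "(empty regulon)", md5 = ""))
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
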