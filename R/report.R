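# Report bundle: the tables and figure shapes of the study's outputs
# (monthly TLIc boxplots, UPGMA dendrogram, stacked functional composition,
# correlation table, regression with confidence band, triangular beta plot).

ternary_xy <- function(sim, repl, rich) {
  # vertices: Sim (0,0), Repl (1,0), RichDiff (0.5, sqrt(3)/2)
  list(x = repl + rich / 2, y = rich * sqrt(3) / 2)
}

plot_triangle <- function(triads, main = "Beta-diversity triads") {
  plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.08, 0.95), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = main)
  polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.05),
       c("Sim", "Repl", "RichDiff"))
  pt <- ternary_xy(triads$sim, triads$repl, triads$rich)
  points(pt$x, pt$y, pch = 16, cex = 0.6, col = "grey30")
  mt <- attr(triads, "mean_triad")
  mpt <- ternary_xy(mt[["sim"]], mt[["repl"]], mt[["rich"]])
  points(mpt$x, mpt$y, pch = 17, cex = 1.6, col = "red")
}

#' Render the full report bundle
#'
#' Writes seven CSV tables, six PDF figures, a weights JSON and a manifest
#' listing every artifact with the configuration hash. CSV tables are
#' byte-identical across reruns with the same inputs.
#'
#' @param dataset `synthetic_dataset` (or list with `community`, `traits`,
#'   `environment`, `config`).
#' @param tli `tli_result` for the dataset's samples.
#' @param fd `fd_result` for the dataset's samples.
#' @param beta `beta_decomposition` (taxonomic level).
#' @param outdir output directory.
#' @return invisibly, the manifest as a data.frame.
#' @export
render_report <- function(dataset, tli, fd, beta, outdir) {
  stages <- list(dataset = dataset, tli = tli, fd = fd, beta = beta)
  for (nm in names(stages))
    if (is.null(stages[[nm]]))
      rfd_stop("dependency_error", "missing stage output: %s", nm)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  community <- dataset$community
  traits <- dataset$traits

  tables <- character(0)
  tab <- function(name, df) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    tables <<- c(tables, p)
  }
  tab("tli_result.csv", as.data.frame(tli))
  tab("fd_result.csv", as.data.frame(fd))
  space <- trait_pcoa(trait_distance(traits))
  tab("trait_space.csv", data.frame(taxon = rownames(space$coords),
                                    space$coords, row.names = NULL))
  comp <- do.call(rbind, lapply(TRAIT_CATEGORIES, function(cat)
    composition_by_modality(community, traits, cat)))
  tab("composition.csv", comp)
  tab("dominance.csv", dominance_screen(community, traits))
  triads <- triad_table(beta)
  tab("beta_triads_taxonomic.csv", triads)
  tab("beta_summary.csv", data.frame(
    family = beta$family,
    mean_D = beta$means[["D"]], mean_repl = beta$means[["repl"]],
    mean_rich = beta$means[["rich"]],
    repl_pct = beta$contributions[["repl_pct"]],
    rich_pct = beta$contributions[["rich_pct"]]))

  wpath <- file.path(outdir, "weights.json")
  jsonlite::write_json(as.list(attr(tli, "weights")), wpath, auto_unbox = TRUE,
                       digits = NA)

  merged <- merge(as.data.frame(tli)[c("sample_id", "tlic")],
                  as.data.frame(fd), by = "sample_id")
  merged <- merge(merged, community[community_meta_cols], by = "sample_id")

  figures <- character(0)
  fig <- function(name, code) {
    p <- file.path(outdir, name)
    pdf(p, width = 7, height = 5)
    on.exit(dev.off(), add = TRUE)
    force(code)
    figures <<- c(figures, p)
  }
  fig("fig_tlic_monthly.pdf",
      boxplot(tlic ~ month, merged, xlab = "Month", ylab = "TLIc",
              main = "Composite trophic level index by month"))
  bc <- braycurtis_matrix(community)
  fig("fig_dendrogram.pdf",
      plot(cluster_samples(bc)$hclust, hang = -1, cex = 0.5,
           main = "UPGMA on Bray-Curtis", xlab = "", sub = ""))
  fig("fig_composition.pdf", {
    cmp <- composition_matrix(community, traits, "feeding")
    frac <- cmp / pmax(rowSums(cmp), 1e-12)
    barplot(t(frac), col = grDevices::grey.colors(ncol(frac)), border = NA,
            names.arg = rep("", nrow(frac)),
            main = "Feeding-habit composition", ylab = "Fraction")
  })
  fig("fig_correlation.pdf", {
    vars <- merged[c("tlic", "S", "fric", "feve", "fdiv")]
    cm <- cor(vars, use = "pairwise.complete.obs")
    graphics::image(seq_len(ncol(cm)), seq_len(ncol(cm)), t(cm[rev(seq_len(ncol(cm))), ]),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    main = "Pearson correlations")
    axis(1, seq_len(ncol(cm)), colnames(cm)); axis(2, seq_len(ncol(cm)), rev(colnames(cm)))
  })
  fig("fig_regression.pdf", {
    ok <- complete.cases(merged$tlic, merged$feve)
    reg <- simple_regression(merged$tlic[ok], merged$feve[ok])
    ord <- order(reg$band$x)
    plot(merged$tlic[ok], merged$feve[ok], pch = 16, col = "grey40",
         xlab = "TLIc", ylab = "FEve",
         main = sprintf("FEve ~ TLIc (slope %.3g, R2 %.3f, p %.3g)",
                        reg$slope, reg$r2, reg$p))
    polygon(c(reg$band$x[ord], rev(reg$band$x[ord])),
            c(reg$band$lwr[ord], rev(reg$band$upr[ord])),
            col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    lines(reg$band$x[ord], reg$band$fit[ord], col = "steelblue", lwd = 2)
  })
  fig("fig_triangle.pdf", plot_triangle(triads))

  cfg <- dataset$config
  cfg_json <- jsonlite::toJSON(
    if (!is.null(cfg)) unclass(cfg) else list(), auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- data.frame(
    file = basename(c(tables, figures, wpath)),
    kind = c(rep("table", length(tables)), rep("figure", length(figures)), "json"),
    config_hash = cfg_hash, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
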