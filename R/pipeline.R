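# One-command reproduction of the full analysis layout: diversity table,
# pairwise Phi_ST / gene-flow table, AMOVA table, neutrality + mismatch
# table (with expansion dating), network export, and a JSON manifest.

pkg_version <- function() as.character(utils::packageVersion("mitopop"))

write_tsv_report <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mitopop %s  seed=%s", pkg_version(),
                     format(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the full pipeline
#'
#' @param fasta Path to the aligned FASTA input.
#' @param popmap Path to the sample-to-population TSV.
#' @param groups Named list pooling base labels, e.g.
#'   `list(ES = c("E", "S"))`; the AMOVA and mismatch stages run on the
#'   pooled labels, the pairwise stage on both base and pooled labels.
#' @param n_perm Permutations for AMOVA / pairwise Phi_ST.
#' @param n_sims Coalescent replicates for neutrality p-values.
#' @param rate_per_site_per_year Divergence rate for expansion dating.
#' @param epsilon Median-joining relaxation parameter.
#' @param seed Mandatory RNG seed.
#' @param out_dir Output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta, popmap, groups = NULL, n_perm = 10000,
                       n_sims = 1000, rate_per_site_per_year = 3.6e-8,
                       epsilon = 0, seed, out_dir) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(fasta = fasta, popmap = popmap, groups = groups,
                 n_perm = n_perm, n_sims = n_sims,
                 rate_per_site_per_year = rate_per_site_per_year,
                 epsilon = epsilon, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Reads and masks the alignment, collapses haplotypes, and writes five
#' artifacts to `cfg$out_dir`: `diversity.tsv`, `pairwise_fst.tsv`,
#' `amova.tsv`, `demography.tsv`, `network.tsv` (+ `network.graphml`), and
#' `manifest.json` recording versions, seed and every parameter. Numbers
#' in TSV reports are rounded for display (pi to 4 dp, Phi_ST and Nm to
#' 3 dp, years to integers); the JSON manifest keeps full precision.
#'
#' @param cfg A [run_config()].
#' @return Invisible list with all in-memory results.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  result <- tryCatch({
    a <- read_fasta(cfg$fasta)
    pm0 <- read_popmap(cfg$popmap)
    a <- mask_sites(a)
    pm <- match_popmap(a, pm0)
    pooled <- if (!is.null(cfg$groups)) pool_populations(pm, cfg$groups)
              else pm
    d <- pairwise_differences(a)

    stage <- "diversity"
    div <- diversity_table(a, pm)
    div_out <- transform(div, h = round(h, 4), se_h = round(se_h, 4),
                         pi = round(pi, 4), se_pi = round(se_pi, 4),
                         k_hat = round(k_hat, 3))
    write_tsv_report(div_out, file.path(cfg$out_dir, "diversity.tsv"),
                     cfg$seed)

    stage <- "fst"
    fst_rows <- list()
    add_fst <- function(label, fst, p) {
      nm <- tryCatch(gene_flow(fst), error = function(e)
        list(nm = NA_real_, category = NA_character_))
      data.frame(comparison = label, fst = round(fst, 3),
                 p_value = round(p, 4), nm = round(nm$nm, 3),
                 category = nm$category, stringsAsFactors = FALSE)
    }
    fm <- phist_matrix(d, pm, n_perm = cfg$n_perm,
                       seed = sub_seed(cfg$seed, 11))
    prs <- utils::combn(fm$populations, 2)
    for (i in seq_len(ncol(prs))) {
      pr <- prs[, i]
      fst_rows[[length(fst_rows) + 1]] <-
        add_fst(paste(pr, collapse = "-"), fm$fst[pr[1], pr[2]],
                fm$p[pr[1], pr[2]])
    }
    overall <- amova_two_level(d, pm, n_perm = cfg$n_perm,
                               seed = sub_seed(cfg$seed, 12))
    fst_rows[[length(fst_rows) + 1]] <-
      add_fst(paste(sort(unique(pm)), collapse = ""), overall$fst,
              overall$p_value)
    amova_pooled <- NULL
    if (!identical(pooled, pm)) {
      amova_pooled <- amova_two_level(d, pooled, n_perm = cfg$n_perm,
                                      seed = sub_seed(cfg$seed, 13))
      fst_rows[[length(fst_rows) + 1]] <-
        add_fst(paste(sort(unique(pooled)), collapse = "-"),
                amova_pooled$fst, amova_pooled$p_value)
    }
    fst_df <- do.call(rbind, fst_rows)
    write_tsv_report(fst_df, file.path(cfg$out_dir, "pairwise_fst.tsv"),
                     cfg$seed)

    stage <- "amova"
    am <- if (!is.null(amova_pooled)) amova_pooled else overall
    amova_df <- data.frame(
      source = c("Between populations", "Within populations"),
      df = c(am$df_among, am$df_within),
      ssd = round(c(am$ssd_among, am$ssd_within), 3),
      variance = round(c(am$sigma2_a, am$sigma2_w), 3),
      pct_variation = round(c(am$pct_among, am$pct_within), 2),
      fst = c(round(am$fst, 3), NA),
      p_value = c(round(am$p_value, 4), NA))
    write_tsv_report(amova_df, file.path(cfg$out_dir, "amova.tsv"),
                     cfg$seed)

    stage <- "neutrality_demography"
    demo_groups <- split(names(pooled), unname(pooled))
    demo_rows <- lapply(names(demo_groups), function(g) {
      ids <- demo_groups[[g]]
      sub <- subset_alignment(a, ids)
      st <- count_site_types(sub)
      nd <- nucleotide_diversity(sub)
      td <- tryCatch(tajimas_d(sub, n_sims = cfg$n_sims,
                               seed = sub_seed(cfg$seed, 20 + match(g, names(demo_groups)))),
                     error = function(e) NULL)
      fs <- tryCatch(fus_fs(sub, n_sims = cfg$n_sims,
                            seed = sub_seed(cfg$seed, 40 + match(g, names(demo_groups)))),
                     error = function(e) NULL)
      mm <- observed_mismatch(d, ids)
      fit <- fit_expansion(mm, seed = sub_seed(cfg$seed, 60))
      et <- expansion_time(fit$tau, ncol(a), cfg$rate_per_site_per_year)
      data.frame(population = g, n = length(ids), ti = st$ti, tv = st$tv,
                 pi = round(nd$pi, 4),
                 tajima_d = if (is.null(td)) NA else round(td$D, 3),
                 tajima_p = if (is.null(td)) NA else round(td$p_value, 4),
                 fu_fs = if (is.null(fs)) NA else round(fs$fs, 3),
                 fu_fs_p = if (is.null(fs)) NA else round(fs$p_value, 4),
                 tau = round(fit$tau, 3), theta0 = round(fit$theta0, 3),
                 theta1 = round(fit$theta1, 3), ssd = signif(fit$ssd, 4),
                 t_years = round(et$t_years), stringsAsFactors = FALSE)
    })
    demo_df <- do.call(rbind, demo_rows)
    write_tsv_report(demo_df, file.path(cfg$out_dir, "demography.tsv"),
                     cfg$seed)

    stage <- "network"
    ht <- collapse_haplotypes(a, pm)
    net <- median_joining(ht, epsilon = cfg$epsilon)
    export_network(net, file.path(cfg$out_dir, "network.tsv"), "edge_tsv")
    export_network(net, file.path(cfg$out_dir, "network.graphml"),
                   "graphml")

    stage <- "manifest"
    manifest <- list(
      tool = "mitopop", version = pkg_version(),
      r_version = as.character(getRversion()),
      seed = cfg$seed,
      parameters = list(n_perm = cfg$n_perm, n_sims = cfg$n_sims,
                        rate_per_site_per_year = cfg$rate_per_site_per_year,
                        epsilon = cfg$epsilon,
                        groups = cfg$groups),
      inputs = list(fasta = cfg$fasta, popmap = cfg$popmap,
                    n_samples = nrow(a), n_sites = ncol(a)),
      results = list(overall_fst = overall$fst,
                     overall_p = overall$p_value,
                     pooled_fst = if (!is.null(amova_pooled))
                       amova_pooled$fst else NULL,
                     n_haplotypes = length(ht$sequences)))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    list(alignment = a, popmap = pm, pooled = pooled, diversity = div,
         fst_table = fst_df, amova = am, overall_amova = overall,
         demography = demo_df, haplotypes = ht, network = net,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
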