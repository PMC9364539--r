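# Cross-analysis intersections (DEGs x trait-correlated genes x GWAS obesity
# genes x modules) and the end-to-end pipeline.

GWAS_DELIMITERS <- c(",", ";", " - ", " x ")

#' Match GWAS-catalog mapped-gene fields against mouse symbols
#'
#' Each raw `MAPPED_GENE` field is split on the catalog's delimiters
#' (`","`, `";"`, `" - "`, `" x "`), tokens are whitespace-stripped and
#' upper-cased, and the token set is intersected with the (already
#' normalized) mouse symbols. Unmatchable tokens never silently match.
#'
#' @param catalog a [read_gwas_catalog()] data.frame.
#' @param mouse_symbols character vector of mouse gene symbols.
#' @param delimiters override the delimiter set.
#' @return list: `matched` (sorted unique matched symbols), `per_row`
#'   (data.frame: row, trait_label, token, matched).
#' @export
match_gwas_genes <- function(catalog, mouse_symbols,
                             delimiters = GWAS_DELIMITERS) {
  symbols <- unique(toupper(trimws(mouse_symbols)))
  rx <- paste(vapply(delimiters, function(d)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", d), character(1)), collapse = "|")
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    toks <- strsplit(catalog$mapped_gene_field[i], rx)[[1]]
    toks <- unique(toupper(gsub("\\s+", "", toks)))
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    rows[[i]] <- data.frame(row = i, trait_label = catalog$trait_label[i],
                            token = toks, matched = toks %in% symbols,
                            stringsAsFactors = FALSE)
  }
  per_row <- do.call(rbind, rows)
  if (is.null(per_row))
    per_row <- data.frame(row = integer(0), trait_label = character(0),
                          token = character(0), matched = logical(0))
  list(matched = sort(unique(per_row$token[per_row$matched])),
       per_row = per_row)
}

#' Disjoint Venn regions of 2-4 named gene sets
#'
#' @param named_sets named list of 2 to 4 character vectors.
#' @return list: `regions` (data.frame: region label like `"A&B"`,
#'   membership pattern, count), `members` (list of per-region gene vectors),
#'   `union_size`.
#' @export
intersect_gene_sets <- function(named_sets) {
  k <- length(named_sets)
  if (k < 2 || k > 4) stop("need 2 to 4 sets")
  nm <- names(named_sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("sets must be named")
  sets <- lapply(named_sets, unique)
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, nm))
  pat <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  labs <- unlist(lapply(seq_len(k), function(m)
    combn(nm, m, paste, collapse = "&", simplify = TRUE)))
  counts <- setNames(integer(length(labs)), labs)
  tab <- table(pat)
  counts[names(tab)] <- as.integer(tab)
  members <- lapply(labs, function(l) sort(all_genes[pat == l]))
  names(members) <- labs
  list(regions = data.frame(region = labs, count = unname(counts),
                            stringsAsFactors = FALSE),
       members = members, union_size = length(all_genes))
}

#' Per-module gene composition across analyses
#'
#' For each module: total genes, count and fraction of genes correlated with
#' the focal trait (nominal p < 0.05 in the correlation table), diet DEGs,
#' strain DEGs, and GWAS-trait genes; plus counts of (diet-only,
#' strain-only, both) DEGs among the trait-correlated, GWAS-matched genes.
#' Genes in no module are reported under module 0 ("not assigned").
#'
#' @param labels named per-gene module labels over the filtered universe.
#' @param gene_symbols symbols aligned with `labels`.
#' @param correlation_table [correlate_expression_with_traits()] rows for the
#'   focal trait (e.g. body fat %).
#' @param de_diet,de_strain [call_diet_degs()] / [call_strain_degs()] tables.
#' @param gwas_symbols matched symbol set from [match_gwas_genes()].
#' @return list: `composition` (per-module counts/fractions),
#'   `deg_categories` (per-module diet-only / both / strain-only counts among
#'   trait-correlated GWAS genes).
#' @export
module_composition <- function(labels, gene_symbols, correlation_table,
                               de_diet, de_strain, gwas_symbols = character(0)) {
  fid <- names(labels)
  corr_sig <- fid %in% correlation_table$feature_id[correlation_table$significant %in% TRUE]
  diet_de <- fid %in% de_diet$feature_id[de_diet$de]
  strain_de <- fid %in% de_strain$feature_id[de_strain$de]
  gwas <- toupper(gene_symbols) %in% toupper(gwas_symbols)
  mods <- sort(unique(labels))
  comp <- do.call(rbind, lapply(mods, function(m) {
    in_m <- labels == m
    tot <- sum(in_m)
    data.frame(module = m,
               color = module_colors(m),
               total_genes = tot,
               trait_correlated = sum(corr_sig & in_m),
               frac_trait_correlated = sum(corr_sig & in_m) / tot,
               diet_degs = sum(diet_de & in_m),
               frac_diet_degs = sum(diet_de & in_m) / tot,
               strain_degs = sum(strain_de & in_m),
               frac_strain_degs = sum(strain_de & in_m) / tot,
               gwas_genes = sum(gwas & in_m),
               stringsAsFactors = FALSE)
  }))
  comp$color[comp$module == 0] <- "not assigned"
  focal <- corr_sig & gwas
  cats <- do.call(rbind, lapply(mods, function(m) {
    in_m <- labels == m & focal
    data.frame(module = m, color = module_colors(m),
               diet_only = sum(in_m & diet_de & !strain_de),
               diet_and_strain = sum(in_m & diet_de & strain_de),
               strain_only = sum(in_m & strain_de & !diet_de),
               stringsAsFactors = FALSE)
  }))
  cats$color[cats$module == 0] <- "not assigned"
  list(composition = comp, deg_categories = cats)
}

#' Run the whole analysis pipeline on simulated or loaded data
#'
#' Executes QC -> TC-ID filtering -> trait correlations -> diet and strain
#' differential expression (-> optional gene-set enrichment) -> heritability
#' and variance partitioning -> network module detection with module-trait
#' statistics -> cross-analysis intersections, writing every report as TSV
#' into `outdir` together with a JSON run manifest (seed, config echo, stage
#' timings). A rerun with the same config and seed is bit-identical.
#'
#' @param sim a [sim_config()] to simulate inputs, or `NULL` to load files.
#' @param expression_path,metadata_path,phenotype_path input TSVs, used when
#'   `sim` is `NULL`.
#' @param outdir output directory; created if needed. `NULL` skips writing.
#' @param net a [network_config()]. The default pins the soft power at the
#'   study condition beta = 5; set `beta = NULL` to choose it by the
#'   scale-free fit criterion instead.
#' @param gene_sets optional [read_gene_sets()] collection for enrichment.
#' @param gwas optional [read_gwas_catalog()] data.frame.
#' @param trait focal phenotype for composition tables.
#' @param pov_features optional feature subset for REML partitioning.
#' @return (invisibly) list with every stage result: `qc`, `filter`,
#'   `correlations`, `de_diet`, `de_strain`, `enrichment`, `heritability`,
#'   `herit_summary`, `pov`, `pov_summary`, `network`, `module_trait`,
#'   `me_tests`, `composition`, `venn`, `manifest`.
#' @export
run_pipeline <- function(sim = NULL, expression_path = NULL,
                         metadata_path = NULL, phenotype_path = NULL,
                         outdir = NULL, net = network_config(beta = 5),
                         gene_sets = NULL, gwas = NULL,
                         trait = "body_fat_pct", pov_features = NULL) {
  t_start <- Sys.time()
  timings <- c()
  tick <- function(nm, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    timings[[nm]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    val
  }
  if (is.null(sim)) {
    if (is.null(expression_path) || is.null(metadata_path))
      stop("config error: provide either a simulation config or input paths")
    loaded <- tick("load", load_dataset(expression_path, metadata_path,
                                        phenotype_path))
    dataset <- loaded$dataset; phen <- loaded$phenotypes
  } else {
    simres <- tick("simulate", simulate_dataset(sim))
    dataset <- simres$dataset; phen <- simres$phenotypes
  }

  qc <- tick("qc", remove_outlier_arrays(dataset))
  filt <- tick("filter", filter_tcids(qc$dataset))
  ds <- filt$dataset

  corr <- tick("correlate", correlate_expression_with_traits(ds, phen))
  de_d <- tick("de_diet", call_diet_degs(ds))
  de_s <- tick("de_strain", call_strain_degs(ds))

  enr <- NULL
  if (!is.null(gene_sets)) {
    enr <- tick("enrich", list(
      diet = overrepresentation_test(de_d$gene_symbol[de_d$de],
                                     ds$gene_symbols, gene_sets),
      strain = overrepresentation_test(de_s$gene_symbol[de_s$de],
                                       ds$gene_symbols, gene_sets)))
  }

  herit <- tick("heritability", heritability_all(ds))
  groups <- list(all = herit$feature_id,
                 diet_degs = de_d$feature_id[de_d$de],
                 strain_degs = de_s$feature_id[de_s$de])
  hsum <- summarize_heritability(herit, groups)
  pov <- tick("pov", partition_variance_all(ds, features = pov_features))
  psum <- summarize_pov(pov, groups = lapply(groups, intersect, pov$feature_id))

  netres <- tick("network", detect_modules(ds, net))
  mt <- NULL; met <- NULL
  if (!is.null(netres$module_set)) {
    mt <- module_trait_correlation(netres$module_set, phen)
    met <- me_group_tests(netres$module_set, ds$metadata)
  }

  gwas_match <- if (!is.null(gwas))
    match_gwas_genes(gwas, ds$gene_symbols)$matched else character(0)
  focal_corr <- corr[corr$trait == trait, , drop = FALSE]
  compo <- tick("integrate", module_composition(
    netres$labels, ds$gene_symbols, focal_corr, de_d, de_s, gwas_match))

  venn_sets <- list(
    diet_degs = de_d$gene_symbol[de_d$de],
    strain_degs = de_s$gene_symbol[de_s$de],
    trait_correlated = focal_corr$gene_symbol[focal_corr$significant %in% TRUE])
  if (length(gwas_match)) venn_sets$gwas <- gwas_match
  venn <- intersect_gene_sets(venn_sets)

  manifest <- list(
    seed = if (!is.null(sim)) sim$seed else NA,
    simulated = !is.null(sim),
    n_samples_input = n_samples(dataset),
    n_samples_after_qc = n_samples(qc$dataset),
    n_features_input = n_features(dataset),
    n_genes_after_filter = n_features(ds),
    beta = netres$beta,
    n_modules = if (is.null(netres$module_set)) 0L else
      ncol(netres$module_set$eigengenes),
    stage_seconds = as.list(timings),
    total_seconds = round(as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs")), 3))

  res <- list(qc = qc$qc, filter = filt$report, correlations = corr,
              de_diet = de_d, de_strain = de_s, enrichment = enr,
              heritability = herit, herit_summary = hsum, pov = pov,
              pov_summary = psum, network = netres, module_trait = mt,
              me_tests = met, composition = compo, venn = venn,
              manifest = manifest, dataset = ds, phenotypes = phen)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    wt <- function(x, nm) if (!is.null(x))
      write.table(x, file.path(outdir, nm), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(res$qc, "qc_report.tsv")
    wt(res$filter, "filter_report.tsv")
    wt(res$correlations, "trait_correlations.tsv")
    wt(res$de_diet, "de_diet.tsv")
    wt(res$de_strain, "de_strain.tsv")
    if (!is.null(enr)) {
      wt(enr$diet, "enrichment_diet.tsv"); wt(enr$strain, "enrichment_strain.tsv")
    }
    wt(res$heritability, "heritability.tsv")
    wt(res$herit_summary, "heritability_summary.tsv")
    wt(res$pov, "variance_partition.tsv")
    wt(res$pov_summary, "variance_partition_summary.tsv")
    wt(data.frame(feature_id = names(netres$labels), module = netres$labels,
                  color = module_colors(netres$labels)), "module_labels.tsv")
    if (!is.null(netres$soft_threshold))
      wt(netres$soft_threshold, "soft_threshold.tsv")
    if (!is.null(netres$module_set))
      wt(cbind(sample_id = rownames(netres$module_set$eigengenes),
               as.data.frame(netres$module_set$eigengenes)),
         "module_eigengenes.tsv")
    wt(mt, "module_trait_correlations.tsv")
    wt(met, "me_group_tests.tsv")
    wt(compo$composition, "module_composition.tsv")
    wt(compo$deg_categories, "module_deg_categories.tsv")
    wt(venn$regions, "venn_regions.tsv")
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
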