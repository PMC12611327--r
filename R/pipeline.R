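#' Run the full integration pipeline end to end
#'
#' Orchestrates simulate (or load) -> depth filter -> differential
#' methylation (genotype and diet, per region) -> DE tables ->
#' expression-linked CpG discovery (local and distal) -> DMR chaining ->
#' regulatory enrichment -> amyloid (PAC) modelling -> choline-protected
#' gene sets, writing every stage's table plus a machine-readable manifest
#' (parameters, per-stage child seeds, md5 of each output) under
#' \code{out_dir}. Reruns with the same configuration and inputs are
#' bit-identical.
#'
#' @param out_dir output directory (created).
#' @param sim a [simulationConfig()] used to generate inputs; ignored when
#'   \code{input_dir} is given.
#' @param input_dir directory laid out as written by
#'   [simulateStudy()]\code{(cfg, dir)}; required files are checked up
#'   front and a missing one is a startup error naming it.
#' @param seed master seed; fanned out to per-stage child seeds.
#' @param thresholds named list overriding the study defaults
#'   (\code{min_depth} 10, \code{max_depth_quantile} 0.999,
#'   \code{min_sample_frac} 0.5, \code{q_dmc} 0.05, \code{min_delta_local}
#'   2.5, \code{min_delta_distal} 5, \code{min_lfc} 0.1, \code{top_n_degs}
#'   1000, \code{cis_tss_window} 5000, \code{max_gap} 500, \code{min_cpgs}
#'   2, \code{enrich_window} 1000, \code{n_perm} 200, \code{top_n_protected}
#'   2000).
#' @param contrasts contrasts to run.
#' @param enrich_labels regulatory element classes tested.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(out_dir, sim = simulationConfig(), input_dir = NULL,
                        seed = NULL, thresholds = list(),
                        contrasts = c("genotype", "diet"),
                        enrich_labels = c("EnhD", "CTCF")) {
  th <- utils::modifyList(list(
    min_depth = 10, max_depth_quantile = 0.999, min_sample_frac = 0.5,
    q_dmc = 0.05, min_delta_local = 2.5, min_delta_distal = 5,
    min_lfc = 0.1, top_n_degs = 1000L, cis_tss_window = 5000L,
    max_gap = 500L, min_cpgs = 2L, enrich_window = 1000L, n_perm = 200L,
    top_n_protected = 2000L), thresholds)
  stopifnot(all(vapply(th, function(v) is.numeric(v) && v > 0, logical(1))))
  if (is.null(seed)) seed <- if (!is.null(sim$seed)) sim$seed else 1L
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, thresholds = th, stages = list(),
                   completed = character())
  results <- list()
  tpath <- function(nm) file.path(out_dir, paste0(nm, ".tsv"))
  emit <- function(stage, tables, params = list()) {
    paths <- character()
    for (nm in names(tables)) {
      writeResultsTable(tables[[nm]], tpath(nm))
      paths[nm] <- tpath(nm)
    }
    manifest$stages[[stage]] <<- list(
      params = params,
      child_seed = seed + (length(manifest$completed) + 1L) * 1000L,
      outputs = as.list(tools::md5sum(paths)))
    manifest$completed <<- c(manifest$completed, stage)
    .write_manifest(manifest, out_dir)
  }

  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$stages[[stage]] <<- list(error = conditionMessage(e))
      .write_manifest(manifest, out_dir)
      stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  run_stage("inputs", function() {
    if (!is.null(input_dir)) {
      study <- .load_study(input_dir)
    } else {
      sim$seed <- seed
      study <- simulateStudy(sim)
    }
    results$study <<- study
    emit("inputs", list(samples = study$samples),
         params = list(source = if (is.null(input_dir)) "simulated"
                       else input_dir))
  })
  study <- results$study
  regions <- unique(study$samples$region)
  genes_gr <- geneModel(study$genes)

  # -- per-region stages ----------------------------------------------------
  all_ecpgs <- list(); all_dmcs <- list()
  filtered <- list()
  for (r in regions) {
    sel <- study$samples$region == r
    mm_r <- study$mm[, sel]
    run_stage(paste0("filter_", r), function() {
      f <- filterSites(mm_r, th$min_depth, th$max_depth_quantile,
                       th$min_sample_frac)
      filtered[[r]] <<- f
      emit(paste0("filter_", r),
           list(), params = list(n_sites_in = nrow(mm_r),
                                 n_sites_kept = nrow(f)))
    })
    for (ct in contrasts) {
      key <- paste0(ct, "_", r)
      run_stage(paste0("dmc_", key), function() {
        dmc <- testDmc(filtered[[r]], contrast = ct, genes = genes_gr,
                       q_cutoff = th$q_dmc)
        all_dmcs[[key]] <<- dmc
        dmg <- summarizeDmgs(dmc)
        out <- list(); out[[paste0("dmc_", key)]] <- dmc
        out[[paste0("dmg_", key)]] <- dmg
        emit(paste0("dmc_", key), out,
             params = list(contrast = ct, region = r,
                           n_dmcs = sum(dmc$is_dmc)))
      })
      run_stage(paste0("ecpg_", key), function() {
        de <- study$expr$de[[r]][[ct]]
        vst_r <- study$expr$vst[, sel, drop = FALSE]
        loc <- runIntegration("local", all_dmcs[[key]], de, vst_r,
                              filtered[[r]],
                              min_delta = th$min_delta_local,
                              min_lfc = th$min_lfc)
        dis <- runIntegration("distal", all_dmcs[[key]], de, vst_r,
                              filtered[[r]], genes = genes_gr,
                              min_delta = th$min_delta_distal,
                              top_n_degs = th$top_n_degs,
                              cis_tss_window = th$cis_tss_window,
                              min_lfc = th$min_lfc)
        ec <- rbind(loc, dis)
        all_ecpgs[[key]] <<- ec
        out <- list(); out[[paste0("ecpg_", key)]] <- ec
        emit(paste0("ecpg_", key), out,
             params = list(n_local = sum(loc$is_ecpg),
                           n_distal = sum(dis$is_ecpg)))
      })
      run_stage(paste0("dmr_", key), function() {
        dmr <- buildDmrs(all_ecpgs[[key]], max_gap = th$max_gap,
                         min_cpgs = th$min_cpgs)
        out <- list(); out[[paste0("dmr_", key)]] <- dmr
        if (nrow(dmr)) writeDmrBed(dmr, file.path(out_dir,
                                                  paste0("dmr_", key, ".bed")))
        emit(paste0("dmr_", key), out, params = list(n_dmrs = nrow(dmr)))
      })
    }
    run_stage(paste0("enrich_", r), function() {
      ec <- do.call(rbind, all_ecpgs[paste0(contrasts, "_", r)])
      ec <- ec[ec$is_ecpg & ec$scope == "distal", , drop = FALSE]
      uni <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(cpgSites(filtered[[r]]))),
        pos = BiocGenerics::start(cpgSites(filtered[[r]])))
      enr <- if (nrow(ec) >= 3) do.call(rbind, lapply(enrich_labels,
        function(lb) as.data.frame(permutationOverlapTest(
          unique(ec[, c("chrom", "pos")]), uni, study$track, lb,
          window = th$enrich_window, n_perm = th$n_perm,
          seed = seed + 17L)))) else
        data.frame(label = character(), n_ecpgs = integer(),
                   observed_overlaps = integer(), perm_mean = numeric(),
                   perm_sd = numeric(), z = numeric(),
                   empirical_p = numeric(), median_distance = numeric())
      out <- list(); out[[paste0("enrichment_", r)]] <- enr
      emit(paste0("enrich_", r), out)
    })
    run_stage(paste0("pac_", r), function() {
      ec <- do.call(rbind, all_ecpgs[paste0(contrasts, "_", r)])
      ec <- unique(ec[ec$is_ecpg, c("chrom", "pos")])
      out <- list()
      if (nrow(ec)) {
        pac <- testPacs(filtered[[r]], ec)
        out[[paste0("pac_", r)]] <- pac
        cls <- tryCatch(classifyDietSpecific(filtered[[r]], ec),
                        error = function(e) NULL)
        if (!is.null(cls)) out[[paste0("pac_diet_", r)]] <- cls
      }
      emit(paste0("pac_", r), out)
    })
    run_stage(paste0("protect_", r), function() {
      pg <- protectedGenes(study$expr$de[[r]]$genotype,
                           study$expr$de[[r]]$genotype_supplemented,
                           top_n = th$top_n_protected)
      dmg <- summarizeDmgs(all_dmcs[[paste0("genotype_", r)]])
      ov <- joinProtectionMethylation(pg, dmg)
      out <- list()
      out[[paste0("protected_", r)]] <- pg
      out[[paste0("protection_overlap_", r)]] <-
        data.frame(region = r, n_protected = ov$n_protected,
                   n_overlap = ov$n_overlap, fraction = ov$fraction)
      emit(paste0("protect_", r), out,
           params = list(fraction_methylated = ov$fraction))
    })
  }
  results$manifest <- manifest
  invisible(results)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

# Load a study directory written by simulateStudy(cfg, dir).
.load_study <- function(dir) {
  need <- c("samples.tsv", "genes.tsv", "ccre.bed", "vst.tsv", "counts.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("input_dir is missing required file '", f, "'")
  bg <- list.files(file.path(dir, "bedgraph"), full.names = TRUE,
                   pattern = "\\.bedGraph$")
  if (!length(bg)) stop("input_dir is missing 'bedgraph/' sample files")
  samples <- readSampleTable(file.path(dir, "samples.tsv"))
  mm <- readMethylationBedGraph(bg)
  mm <- mm[, match(samples$sample_id, colnames(mm))]
  SummarizedExperiment::colData(mm) <- S4Vectors::DataFrame(
    samples, row.names = samples$sample_id)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  vst_t <- utils::read.delim(file.path(dir, "vst.tsv"), check.names = FALSE)
  vst <- as.matrix(vst_t[, -1]); rownames(vst) <- vst_t$gene_id
  counts_t <- utils::read.delim(file.path(dir, "counts.tsv"),
                                check.names = FALSE)
  counts <- as.matrix(counts_t[, -1]); rownames(counts) <- counts_t$gene_id
  de <- list()
  for (f in list.files(dir, pattern = "^de_.*\\.tsv$")) {
    parts <- strsplit(sub("^de_(.*)\\.tsv$", "\\1", f), "_")[[1]]
    r <- parts[1]; ct <- paste(parts[-1], collapse = "_")
    de[[r]][[ct]] <- utils::read.delim(file.path(dir, f),
                                       stringsAsFactors = FALSE)
  }
  track <- readRegulatoryTrack(file.path(dir, "ccre.bed"))
  list(samples = samples, mm = mm, genes = genes,
       expr = list(vst = vst, counts = counts, de = de), track = track,
       truth = NULL)
}
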