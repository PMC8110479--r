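#' Run the analysis pipeline from a single configuration
#'
#' Orchestrates the stages — simulate (or load pairs), bin + balance,
#' insulation + boundary calling, P(s) scaling, gene blocks/sites, and
#' boundary pileups — in dependency order, writing every artifact plus a
#' manifest with content hashes and an echo of the effective configuration.
#' Identical configuration and seed yield identical hashes for
#' deterministic artifacts. A stage failure aborts with the stage named;
#' artifacts already written are retained.
#'
#' @param config Path to a YAML file or an equivalent nested list. Top-level
#'   keys: `seed`, `output_dir`, `stages` (character vector), `simulate`,
#'   `inputs`, `matrix`, `insulation`, `scaling`, `genes`, `pileup`.
#'   Unknown top-level keys are rejected.
#' @param output_dir Overrides the configured output directory.
#' @return Invisibly, the manifest tibble (`file`, `stage`, `md5`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "output_dir", "stages", "simulate", "inputs", "matrix",
             "insulation", "scaling", "genes", "pileup")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  out_dir <- output_dir %||% config$output_dir %||% "dinochrom_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("simulate", "matrix", "insulation", "scaling", "genes", "pileup")
  manifest <- list()
  note <- function(file, stage) {
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(file = basename(file), stage = stage,
                     md5 = unname(tools::md5sum(file)))
  }
  in_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  note(file.path(out_dir, "config_echo.yaml"), "config")

  genome <- NULL; pairs <- NULL; assembly <- NULL; genes <- NULL
  truth <- NULL; expr_tracks <- NULL

  if ("simulate" %in% stages) {
    in_stage("simulate", {
      sim_args <- config$simulate %||% list()
      with_seq <- isTRUE(sim_args$with_sequence)
      sim_args$with_sequence <- NULL
      sim_args$seed <- sim_args$seed %||% config$seed %||% 1L
      spec <- do.call(synthetic_spec, sim_args)
      genome <- generate_genome(spec, with_sequence = with_seq)
      pairs <- generate_contacts(genome)
      assembly <- genome$assembly
      genes <- genome$genes
      truth <- genome$truth
      expr_tracks <- generate_expression(genes, spec)
      write_pairs(pairs, file.path(out_dir, "contacts.pairs"), assembly)
      write_gff_genes(genes, file.path(out_dir, "genes.gff3"))
      write_bed(dplyr::rename(truth$boundaries, start = "pos")
                |> dplyr::mutate(end = .data$start + 1),
                file.path(out_dir, "planted_boundaries.bed"))
      if (with_seq) write_fasta(assembly, file.path(out_dir, "genome.fa"))
      note(file.path(out_dir, "contacts.pairs"), "simulate")
      note(file.path(out_dir, "genes.gff3"), "simulate")
      note(file.path(out_dir, "planted_boundaries.bed"), "simulate")
    })
  } else {
    in_stage("inputs", {
      inp <- config$inputs
      if (is.null(inp$pairs)) stop("no simulate stage and no inputs$pairs")
      if (!file.exists(inp$pairs)) stop("missing input file: ", inp$pairs)
      pairs <- read_pairs(inp$pairs)
      if (!is.null(inp$fasta)) {
        assembly <- read_fasta(inp$fasta)
      } else if (!is.null(inp$chromsizes)) {
        cs <- readr::read_tsv(inp$chromsizes, col_names = c("name", "length"),
                              col_types = "cd", progress = FALSE)
        assembly <- genome_assembly(cs)
      } else stop("inputs need fasta or chromsizes")
      if (!is.null(inp$genes)) genes <- read_gff_genes(inp$genes)
    })
  }

  cm <- NULL; cfg <- NULL; prof <- NULL; bounds <- NULL
  if ("matrix" %in% stages) {
    in_stage("matrix", {
      mx <- config$matrix %||% list()
      res <- mx$resolution %||% 1e4
      bins <- bin_genome(assembly, res)
      cm <- pairs_to_matrix(pairs, bins)
      cm <- ice_balance(cm, max_iter = mx$max_iter %||% 200,
                        tol = mx$tol %||% 1e-5,
                        mad_filter = mx$mad_filter %||% 5)
      write_triplet_matrix(cm, file.path(out_dir, "matrix"))
      note(file.path(out_dir, "matrix.bins.tsv"), "matrix")
      note(file.path(out_dir, "matrix.triplets.tsv"), "matrix")
      message(sprintf("matrix: %d bins, %d discarded pair(s), %d masked bin(s)",
                      nrow(bins), cm$discards, sum(is.na(cm$weights))))
    })
  }

  if ("insulation" %in% stages) {
    in_stage("insulation", {
      ic <- config$insulation %||% list()
      cfg <- insulation_config(
        window = ic$window %||% 5e5,
        resolution = ic$resolution %||% bin_resolution(cm$bins),
        delta_span = ic$delta_span %||% 1e5,
        strength_min = ic$strength_min %||% 0.2)
      prof <- insulation_score(cm, cfg)
      bounds <- refine_boundaries(call_boundaries(prof, cfg), prof)
      if (!is.null(assembly$seq)) bounds <- contig_filter(bounds, assembly)
      write_bedgraph(
        dplyr::rename(prof[, c("chrom", "start", "end", "score")],
                      value = "score"),
        file.path(out_dir, "insulation.bedGraph"))
      write_bed(dplyr::mutate(tibble::as_tibble(bounds),
                              name = .data$provenance,
                              score = round(.data$strength, 4)),
                file.path(out_dir, "boundaries.bed"))
      note(file.path(out_dir, "insulation.bedGraph"), "insulation")
      note(file.path(out_dir, "boundaries.bed"), "insulation")
      message(sprintf("insulation: %d boundary call(s)", nrow(bounds)))
    })
  }

  if ("scaling" %in% stages) {
    in_stage("scaling", {
      sc <- config$scaling %||% list()
      curve <- ps_from_pairs(pairs, assembly,
                             bin_ratio = sc$bin_ratio %||% 2^(1 / 8))
      readr::write_tsv(tibble::as_tibble(curve),
                       file.path(out_dir, "ps_curve.tsv"), progress = FALSE)
      fit <- fit_exponent(curve, fit_range = c(sc$fit_min %||% 5e4,
                                               sc$fit_max %||% 2e6))
      seg <- segment_regimes(curve, knots = sc$knots %||% 2)
      rep <- dplyr::mutate(tidy(seg), exponent_fit = fit$exponent,
                           exponent_se = fit$se)
      readr::write_tsv(rep, file.path(out_dir, "ps_fit.tsv"),
                       progress = FALSE)
      note(file.path(out_dir, "ps_curve.tsv"), "scaling")
      note(file.path(out_dir, "ps_fit.tsv"), "scaling")
      message(sprintf("scaling: regime exponent %.3f (se %.3f)",
                      fit$exponent, fit$se))
    })
  }

  sites <- NULL
  if ("genes" %in% stages && !is.null(genes)) {
    in_stage("genes", {
      blocks <- find_blocks(genes)
      sites <- call_sites(blocks)
      write_bed(tibble::tibble(chrom = blocks$chrom,
                               start = blocks$span_start,
                               end = blocks$span_end,
                               name = paste0("block", blocks$block_id,
                                             ";size=", blocks$size),
                               score = blocks$size, strand = blocks$strand),
                file.path(out_dir, "gene_blocks.bed"))
      write_bed(tibble::tibble(chrom = sites$chrom,
                               start = floor(sites$pos),
                               end = floor(sites$pos) + 1,
                               name = sites$kind),
                file.path(out_dir, "sites.bed"))
      note(file.path(out_dir, "gene_blocks.bed"), "genes")
      note(file.path(out_dir, "sites.bed"), "genes")
      message(sprintf("genes: %d blocks; %.1f%% of genes in blocks >= 9",
                      nrow(blocks), 100 * block_gene_fraction(blocks, 9)))
    })
  }

  if ("pileup" %in% stages && !is.null(bounds) && nrow(bounds) > 0) {
    in_stage("pileup", {
      pu <- config$pileup %||% list()
      pp <- pileup(cm, bounds, flank = pu$flank %||% 5e5,
                   min_sites = pu$min_sites %||% 10)
      utils::write.table(pp$log10_oe,
                         file.path(out_dir, "pileup_boundaries.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      note(file.path(out_dir, "pileup_boundaries.tsv"), "pileup")
      message(sprintf("pileup: %d site(s) aggregated", pp$n_sites))
    })
  }

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
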