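# Orchestration: load or simulate per-gene alignments, infer gene trees,
# build the RF tree space and GD table, PCS, substitution rates per
# gene/group/region, variation and informativeness, and the 12-panel
# correlation report, merged into one per-gene profile table.

#' Load per-gene FASTA alignments from a directory
#'
#' One FASTA per gene, file name = gene name. Alignments must be rectangular;
#' with `frame_check = TRUE` each must be in frame (length divisible by 3,
#' no internal stop codon in any fully resolved row).
#'
#' @param dir Directory of `.fasta`/`.fa` files.
#' @param frame_check Enforce codon frame?
#' @return Named list of `gene_alignment`s (codon-flagged if `frame_check`).
#' @export
load_gene_alignments <- function(dir, frame_check = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  out <- lapply(files, function(f) {
    gene <- sub("\\.[^.]*$", "", basename(f))
    aln <- tryCatch(read_fasta_alignment(f, gene = gene, codon = frame_check),
                    error = function(e) stop("gene '", gene, "': ",
                                             conditionMessage(e), call. = FALSE))
    if (frame_check) {
      idx <- codon_index_matrix(aln)
      chars <- unclass(aln)
      nc <- ncol(aln) %/% 3L
      for (row in seq_len(nrow(aln))) {
        cods <- vapply(seq_len(nc - 1L), function(cc)
          paste(chars[row, (3L * cc - 2L):(3L * cc)], collapse = ""), "")
        full <- cods %in% names(GENETIC_CODE_AA)
        if (any(full & GENETIC_CODE_AA[cods] == "*"))
          stop("gene '", gene, "', row '", rownames(aln)[row],
               "': internal stop codon", call. = FALSE)
      }
    }
    aln
  })
  names(out) <- vapply(files, function(f) sub("\\.[^.]*$", "", basename(f)), "")
  out
}

#' Concatenate gene alignments over a fixed taxon order
#'
#' Column-wise concatenation in the given gene order; taxa missing a gene
#' receive a gap run of that gene's length. The emitted partition table
#' (attribute `"partitions"`) records each gene's 1-based inclusive
#' coordinate range.
#'
#' @param genes Named list of `gene_alignment`s; every gene's taxa must be a
#'   subset of `taxa`.
#' @param taxa Ordered character vector of output taxa.
#' @return A `gene_alignment` with attribute `partitions` (data frame
#'   `gene`, `start`, `end`).
#' @export
concatenate_alignments <- function(genes, taxa = NULL) {
  stopifnot(length(genes) >= 1L)
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(genes, rownames))))
  lens <- vapply(genes, ncol, 0L)
  for (g in names(genes)) {
    extra <- setdiff(rownames(genes[[g]]), taxa)
    if (length(extra))
      stop("gene '", g, "' has taxa outside the requested set: ",
           paste(extra, collapse = ", "))
  }
  big <- matrix("-", nrow = length(taxa), ncol = sum(lens),
                dimnames = list(taxa, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(genes)) {
    m <- unclass(genes[[i]])
    big[rownames(m), starts[i]:ends[i]] <- m
  }
  codon <- all(vapply(genes, function(g) isTRUE(attr(g, "codon")), TRUE))
  out <- gene_alignment(big, gene = paste(names(genes), collapse = "+"),
                        codon = codon)
  attr(out, "partitions") <- data.frame(gene = names(genes),
                                        start = starts, end = ends,
                                        row.names = NULL)
  out
}

#' Pipeline configuration
#'
#' Exactly one of a real-input block (`alignments_dir`, optionally
#' `gene_trees_file` + `gene_ids_file`, `species_tree_file`, ...) or a
#' simulation block (`simulation = benchmark_config()`) must be present.
#' The seed is mandatory when simulating.
#'
#' @param alignments_dir Directory of per-gene FASTA files (real mode).
#' @param gene_trees_file,gene_ids_file Multi-tree Newick + matching gene ids
#'   (one per line); if omitted in real mode, gene trees are inferred by
#'   JC + neighbor joining.
#' @param species_tree_file Newick of the coalescent species tree (real mode).
#' @param species_tree2_file Optional second species tree (e.g. from
#'   concatenation), used as an extra tree-space point and PCS alternative.
#' @param group_file,region_file Grouping TSVs; defaults to the packaged
#'   plastid template.
#' @param simulation A `benchmark_config` (simulation mode).
#' @param blind In simulation mode, use an NJ tree from the concatenated
#'   matrix as the coalescent species tree instead of the true tree.
#' @param d_max JC distance cap.
#' @param lambda_max Site-rate bound.
#' @param pcs_mode `"nni"` or `"alternative"` (second species tree as the
#'   explicit alternative).
#' @param rf_normalized Feed normalized RF distances into the ordination?
#' @param stages Character subset of
#'   `c("treespace", "pcs", "rates", "groups", "variation", "correlate")`.
#' @param seed Integer seed.
#' @param out_dir Output directory for TSVs, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignments_dir = NULL, gene_trees_file = NULL,
                            gene_ids_file = NULL, species_tree_file = NULL,
                            species_tree2_file = NULL, group_file = NULL,
                            region_file = NULL, simulation = NULL,
                            blind = FALSE, d_max = 5.0, lambda_max = 20,
                            pcs_mode = c("nni", "alternative"),
                            rf_normalized = FALSE,
                            stages = c("treespace", "pcs", "rates", "groups",
                                       "variation", "correlate"),
                            seed = NULL, out_dir = NULL) {
  real <- !is.null(alignments_dir)
  sim <- !is.null(simulation)
  if (real && sim)
    stop("config error: both a real-input block and a simulation block present")
  if (!real && !sim)
    stop("config error: neither a real-input block nor a simulation block present")
  if (sim && is.null(seed)) stop("seed is mandatory when simulating")
  if (sim) validate_benchmark_config(simulation)
  if (real && is.null(species_tree_file))
    stop("real-input mode requires species_tree_file")
  structure(list(alignments_dir = alignments_dir,
                 gene_trees_file = gene_trees_file,
                 gene_ids_file = gene_ids_file,
                 species_tree_file = species_tree_file,
                 species_tree2_file = species_tree2_file,
                 group_file = group_file, region_file = region_file,
                 simulation = simulation, blind = blind, d_max = d_max,
                 lambda_max = lambda_max, pcs_mode = match.arg(pcs_mode),
                 rf_normalized = rf_normalized, stages = stages, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (simulate ->) gene-tree inference (or loading) ->
#' common-taxon restriction -> RF matrix -> PCoA -> GD -> PCS -> NG86 rates
#' (gene, functional group, region) -> variation and informativeness ->
#' 12-panel correlations. Per-gene outputs are merged into one profile table
#' (one row per analyzed gene; genes excluded from a stage carry missing
#' values there). Every pruning/exclusion decision is recorded in the run
#' log. With `out_dir` set, all tables are written as TSV.
#'
#' @param cfg A `pipeline_config`.
#' @return List of class `pipeline_result` with elements `profiles`,
#'   `correlations`, `ordination`, `gd`, `pcs`, `rates_genes`,
#'   `rates_groups`, `variation`, `exclusions`, `log`, and (simulation mode)
#'   `dataset`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  logf <- character(0)
  say <- function(...) logf <<- c(logf, paste0(...))
  say("plastidscape ", as.character(utils::packageVersion("plastidscape")),
      " | R ", R.version$major, ".", R.version$minor)
  cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
                                  collapse = ""))) %% 1e9
  say("seed: ", if (is.null(cfg$seed)) "none" else cfg$seed,
      " | config hash: ", cfg_hash)

  sim_mode <- !is.null(cfg$simulation)
  dataset <- NULL
  if (sim_mode) {
    dataset <- make_benchmark_dataset(cfg$simulation, seed = cfg$seed)
    alignments <- dataset$alignments
    grouping <- list(
      group_map = stats::setNames(cfg$simulation$genes$group, cfg$simulation$genes$gene),
      region_map = stats::setNames(cfg$simulation$genes$region, cfg$simulation$genes$gene))
    say("simulated benchmark: ", length(alignments), " genes, ",
        cfg$simulation$n_taxa, " taxa")
  } else {
    alignments <- load_gene_alignments(cfg$alignments_dir, frame_check = TRUE)
    grouping <- if (!is.null(cfg$group_file))
      read_grouping(cfg$group_file, cfg$region_file) else default_grouping()
    say("loaded ", length(alignments), " gene alignments from ", cfg$alignments_dir)
  }
  gene_names <- names(alignments)
  exclusions <- data.frame(gene = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  exclude <- function(genes, reason) {
    if (length(genes))
      exclusions <<- rbind(exclusions,
                           data.frame(gene = genes, reason = reason,
                                      stringsAsFactors = FALSE))
  }

  # gene trees
  if (!sim_mode && !is.null(cfg$gene_trees_file)) {
    gene_trees <- read_newick_file(cfg$gene_trees_file)
    names(gene_trees) <- readLines(cfg$gene_ids_file, warn = FALSE)
    say("loaded ", length(gene_trees), " gene trees")
  } else {
    gene_trees <- infer_gene_trees(alignments, d_max = cfg$d_max)
    exclude(attr(gene_trees, "skipped"), "fewer than 4 taxa: no gene tree")
    say("inferred ", length(gene_trees), " NJ gene trees (JC distances, cap ",
        cfg$d_max, ")")
  }

  # species trees
  if (sim_mode) {
    concat_all <- concatenate_alignments(alignments)
    concat_tree <- neighbor_joining(
      suppressWarnings(jc_distance_matrix(concat_all, d_max = cfg$d_max)))
    species_tree <- if (cfg$blind) concat_tree else dataset$species_tree
    species_tree2 <- if (cfg$blind) NULL else concat_tree
    say(if (cfg$blind) "blind mode: species tree = NJ on concatenation"
        else "species tree = true simulated tree; second tree = NJ on concatenation")
  } else {
    species_tree <- parse_newick(paste(readLines(cfg$species_tree_file,
                                                 warn = FALSE), collapse = ""))
    species_tree2 <- if (!is.null(cfg$species_tree2_file))
      parse_newick(paste(readLines(cfg$species_tree2_file, warn = FALSE),
                         collapse = "")) else NULL
  }

  profiles <- data.frame(gene = gene_names,
                         group = unname(grouping$group_map[gene_names]),
                         region = unname(grouping$region_map[gene_names]),
                         n_taxa = vapply(alignments, nrow, 0L),
                         stringsAsFactors = FALSE)

  # tree space and GD
  gd <- NULL; ord <- NULL
  if ("treespace" %in% cfg$stages) {
    pool <- gene_trees
    pool[["species_coalescent"]] <- species_tree
    if (!is.null(species_tree2)) pool[["species_concat"]] <- species_tree2
    restricted <- restrict_to_common_taxa(pool, drop_genes = TRUE)
    # species trees are never dropped by the greedy pass in practice (they
    # carry all taxa); guard anyway
    stopifnot("species_coalescent" %in% names(restricted))
    logf <- c(logf, paste0("treespace: ", attr(restricted, "report")))
    dropped <- setdiff(names(pool), names(restricted))
    exclude(setdiff(dropped, c("species_coalescent", "species_concat")),
            "dropped to enlarge common taxon set (tree space)")
    D <- rf_matrix(restricted, normalized = cfg$rf_normalized)
    ord <- pcoa_ordination(D, k = 2L)
    say("PCoA axes 1-2 variance explained: ",
        paste(sprintf("%.1f%%", 100 * ord$variance_explained), collapse = ", "))
    gd <- gene_discordance(ord, "species_coalescent",
                           exclude_ids = "species_concat")
    say("GD mean ", signif(attr(gd, "mean"), 5), ", median ",
        signif(attr(gd, "median"), 5))
    profiles$GD <- gd$GD[match(profiles$gene, gd$gene)]
  }

  # PCS
  pcs <- NULL
  if ("pcs" %in% cfg$stages) {
    alternatives <- if (cfg$pcs_mode == "alternative") {
      if (is.null(species_tree2))
        stop("pcs_mode 'alternative' requires a second species tree")
      list(species_tree2)
    } else "nni"
    pcs <- pcs_scores(gene_trees, species_tree, alternatives = alternatives)
    exclude(attr(pcs, "skipped"), "fewer than 4 shared taxa (PCS)")
    say("PCS (", attr(pcs, "mode"), ", ", attr(pcs, "aggregation"), "): ",
        sum(pcs$class == "positive"), " positive, ",
        sum(pcs$class == "negative"), " negative, ",
        sum(pcs$class == "zero"), " zero")
    profiles$PCS <- pcs$PCS[match(profiles$gene, pcs$gene)]
    profiles$PCS_class <- pcs$class[match(profiles$gene, pcs$gene)]
  }

  # substitution rates
  rates_genes <- NULL; rates_groups <- NULL
  if ("rates" %in% cfg$stages) {
    rates_genes <- do.call(rbind, lapply(gene_names, function(g) {
      a <- alignments[[g]]
      if (nrow(a) < 2L) {
        exclude(g, "fewer than 2 taxa (rates)")
        return(data.frame(unit = g, dN = NA_real_, dS = NA_real_,
                          omega = NA_real_, n_pairs_dN = 0L, n_pairs_dS = 0L,
                          stringsAsFactors = FALSE))
      }
      unit_rates(a, unit = g)
    }))
    profiles$dN <- rates_genes$dN[match(profiles$gene, rates_genes$unit)]
    profiles$dS <- rates_genes$dS[match(profiles$gene, rates_genes$unit)]
    profiles$omega <- rates_genes$omega[match(profiles$gene, rates_genes$unit)]
    if ("groups" %in% cfg$stages) {
      rates_groups <- group_region_rates(alignments, grouping)
      say("group/region rates computed for ", nrow(rates_groups), " units")
    }
  }

  # variation and informativeness
  variation <- NULL
  if ("variation" %in% cfg$stages) {
    clock <- ultrametricize(species_tree)
    variation <- do.call(rbind, lapply(gene_names, function(g) {
      a <- alignments[[g]]
      if (nrow(a) < 2L)
        return(data.frame(gene = g, L = ncol(a), S = NA_integer_,
                          pi = NA_real_, PV = NA_real_, PI_max = NA_real_,
                          t_star = NA_real_, stringsAsFactors = FALSE))
      rec <- variation_record(a, clock, lambda_max = cfg$lambda_max)
      rec$gene <- g
      rec
    }))
    for (cn in c("L", "S", "pi", "PV", "PI_max", "t_star"))
      profiles[[cn]] <- variation[[cn]][match(profiles$gene, variation$gene)]
  }

  # correlations
  correlations <- NULL
  if ("correlate" %in% cfg$stages &&
      all(c("dN", "dS", "omega", "GD", "pi", "PV", "PI_max") %in% names(profiles))) {
    correlations <- rates_vs_characteristics(profiles)
    say("correlations: ", sum(correlations$p < 0.05, na.rm = TRUE),
        "/12 panels with p < 0.05")
  }

  res <- structure(list(profiles = profiles, correlations = correlations,
                        ordination = ord, gd = gd, pcs = pcs,
                        rates_genes = rates_genes, rates_groups = rates_groups,
                        variation = variation, exclusions = exclusions,
                        log = logf, dataset = dataset),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num_fmt <- function(df) {
    for (cn in names(df)) if (is.numeric(df[[cn]]))
      df[[cn]] <- formatC(df[[cn]], digits = 10, format = "g")
    df
  }
  write_tsv(num_fmt(res$profiles), file.path(dir, "gene_profiles.tsv"))
  if (!is.null(res$correlations))
    write_tsv(num_fmt(res$correlations), file.path(dir, "correlations.tsv"))
  if (!is.null(res$ordination)) {
    ord_df <- data.frame(id = res$ordination$ids, res$ordination$coords)
    write_tsv(num_fmt(ord_df), file.path(dir, "ordination.tsv"))
    write_tsv(num_fmt(data.frame(eigenvalue = res$ordination$eigenvalues)),
              file.path(dir, "eigenvalues.tsv"))
  }
  if (!is.null(res$gd)) write_tsv(num_fmt(res$gd), file.path(dir, "discordance.tsv"))
  if (!is.null(res$pcs)) write_tsv(res$pcs, file.path(dir, "pcs.tsv"))
  if (!is.null(res$rates_genes))
    write_tsv(num_fmt(res$rates_genes), file.path(dir, "rates_genes.tsv"))
  if (!is.null(res$rates_groups))
    write_tsv(num_fmt(res$rates_groups), file.path(dir, "rates_groups.tsv"))
  if (!is.null(res$exclusions))
    write_tsv(res$exclusions, file.path(dir, "exclusions.tsv"))
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("plastidscape pipeline result:", nrow(x$profiles), "gene profiles\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
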