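## End-to-end orchestration: one structured YAML config drives the
## simulate / classify / phylo / primers / inventory stages, each
## emitting TSV/JSON/newick/FASTA artifacts plus a run manifest.
## Logging goes to standard error with stage prefixes; reports are
## never mixed into logs.

#' Read and validate a pipeline configuration
#'
#' The configuration is a nestable key-value (YAML) file.  Exactly one of
#' a real-input block (`input:` with FASTA/metadata/inventory paths) or a
#' synthetic block (`synthetic:`) must be present; all seeds are
#' explicit.  Settings mirror the analysis defaults: 7-aa linker/tower
#' deletion regions, amino-acid difference counts with complete deletion
#' and bootstrap for the phylogeny, a 3-nt primer 3' window.
#'
#' @param path Path to a YAML config, or a list already in config shape.
#' @return Validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  has_real <- !is.null(cfg$input)
  has_synth <- !is.null(cfg$synthetic)
  if (has_real == has_synth)
    stop("config must contain exactly one of 'input' or 'synthetic'")
  if (is.null(cfg$seed)) stop("config must set an explicit top-level seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$outdir)) cfg$outdir <- "nirkit_out"
  nj <- cfg$nj
  cfg$nj <- list(
    method = if (is.null(nj$method)) "count_differences" else nj$method,
    deletion = if (is.null(nj$deletion)) "complete" else nj$deletion,
    replicates = if (is.null(nj$replicates)) 100L
                 else as.integer(nj$replicates))
  pr <- cfg$primers
  cfg$primer_settings <- list(
    three_prime_window = if (is.null(pr$three_prime_window)) 3L
                         else as.integer(pr$three_prime_window),
    max_mismatch = if (is.null(pr$max_mismatch)) 2L
                   else as.integer(pr$max_mismatch))
  cfg
}

#' Bundled default pipeline configuration
#'
#' A full synthetic run: generate a two-clade sequence set, classify it,
#' build the bootstrapped NJ tree, evaluate a degenerate primer pair on
#' back-translated genes with planted clade-dependent mismatches, and
#' generate + summarise a genome inventory.  Primer sequences are
#' synthetic stand-ins supplied by the config, not data.
#'
#' @return Path to the YAML file.
#' @export
defaultPipelineConfig <- function() {
  system.file("extdata", "default_config.yaml", package = "nirkit",
              mustWork = TRUE)
}

pipeLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order (`simulate` before anything that needs
#' synthetic inputs).  Each stage writes its artifacts under the output
#' directory; a `manifest.json` (config hash, seeds, package version,
#' artifact list) is written last.  Identical config and seeds give a
#' byte-identical report bundle.
#'
#' @param config Path to a YAML config or a config list; see
#'   [readPipelineConfig()].
#' @param stages Subset of `simulate`, `classify`, `phylo`, `primers`,
#'   `inventory`.
#' @param outdir Optional override of the config's output directory.
#' @return Invisibly, the manifest list.  Errors carry a stage-tagged
#'   diagnostic.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        stages = c("simulate", "classify", "phylo",
                                   "primers", "inventory"),
                        outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- readPipelineConfig(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  art <- function(x) { artifacts <<- c(artifacts, x); x }
  pth <- function(f) file.path(cfg$outdir, f)

  ref <- surrogateReference()
  set <- NULL; truth <- NULL

  if ("simulate" %in% stages) {
    if (is.null(cfg$synthetic))
      stop("[simulate] config has no 'synthetic' block")
    sc <- cfg$synthetic
    gcfg <- seqGenConfig(
      n_clade1 = sc$n_clade1 %||% 10L, n_clade2 = sc$n_clade2 %||% 10L,
      n_bacillus_loop = sc$n_bacillus_loop %||% 0L,
      substitution_rate = sc$substitution_rate %||% 0,
      fraction_with_heme_ext = sc$fraction_with_heme_ext %||% 0.15,
      fraction_with_cupredoxin_ext =
        sc$fraction_with_cupredoxin_ext %||% 0.15,
      multi_copy_fraction = sc$multi_copy_fraction %||% 0.05,
      seed = cfg$seed)
    gen <- generateNirkSet(gcfg)
    set <- gen$set; truth <- gen$truth
    writeFasta(set, art(pth("synthetic_nirk.fasta")))
    writeMetadata(set, art(pth("synthetic_nirk_metadata.tsv")))
    writeFasta(ref, art(pth("reference.fasta")))
    write.table(truth, art(pth("synthetic_truth.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pipeLog("simulate", nrow(truth), " sequences generated")
  }

  loadInputs <- function() {
    if (!is.null(set)) return()
    if (!is.null(cfg$input)) {
      set <<- readFasta(cfg$input$fasta, "protein",
                        metadata = cfg$input$metadata)
      if (!is.null(cfg$input$reference) &&
          !identical(cfg$input$reference, "bundled"))
        ref <<- readFasta(cfg$input$reference, "protein")
    } else {
      stop("stage requires sequences: run 'simulate' first or provide ",
           "an 'input' block")
    }
  }

  cls <- NULL
  if ("classify" %in% stages) {
    loadInputs()
    cls <- classifySequences(set, ref)
    ok <- cls$profiles$is_nirk
    writeProfiles(cls$profiles[ok, , drop = FALSE],
                  art(pth("profiles.tsv")))
    writeProfiles(cls$profiles[ok, , drop = FALSE],
                  art(pth("profiles.json")), format = "json")
    if (any(!ok)) {
      writeProfiles(cls$profiles[!ok, , drop = FALSE],
                    art(pth("rejects.tsv")))
      pipeLog("classify", sum(!ok),
              " sequence(s) failed residue validation -> rejects.tsv")
    }
    pipeLog("classify", sum(ok), " sequences profiled")
  }

  if ("phylo" %in% stages) {
    loadInputs()
    if (is.null(cls)) cls <- classifySequences(set, ref)
    keep <- cls$profiles$id[cls$profiles$is_nirk]
    if (length(keep) < 3L) stop("[phylo] fewer than 3 validated sequences")
    aln <- stackAlignment(cls$maps[keep], set)
    dm <- distanceMatrix(aln, cfg$nj$method, cfg$nj$deletion)
    write.table(dm, art(pth("distance_matrix.tsv")), sep = "\t",
                quote = FALSE, col.names = NA)
    tree <- bootstrapSupport(aln, cfg$nj$method, cfg$nj$deletion,
                             replicates = cfg$nj$replicates,
                             seed = cfg$seed)
    toNewick(tree, art(pth("nj_tree.nwk")))
    pipeLog("phylo", "NJ tree with ", cfg$nj$replicates,
            " bootstrap replicates written")
  }

  if ("primers" %in% stages) {
    loadInputs()
    if (is.null(cls)) cls <- classifySequences(set, ref)
    prims <- cfg$primers$definitions
    if (is.null(prims)) stop("[primers] no primer definitions in config")
    nt <- backtranslate(set, seed = cfg$seed)
    clade_of <- setNames(cls$profiles$clade, cls$profiles$id)
    for (pdef in prims) {
      pr <- primer(pdef$name, pdef$sequence, pdef$orientation)
      planted <- nt
      if (!is.null(cfg$primers$plant_mismatches)) {
        pm <- lapply(cfg$primers$plant_mismatches, unlist)
        planted <- plantPrimerSites(nt, pr, pm, clade_of,
                                    seed = cfg$seed)$set
      }
      prof <- mismatchProfile(pr, planted, clade_of,
                              cfg$primer_settings$three_prime_window)
      write.table(prof, art(pth(sprintf("primer_%s_profile.tsv",
                                        pr@name))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      logo <- bindingRegionLogo(planted, pr)
      write.table(
        data.frame(position = seq_along(logo$ic), t(logo$freq),
                   ic_bits = logo$ic),
        art(pth(sprintf("primer_%s_logo.tsv", pr@name))),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pipeLog("primers", "profile + logo for ", pr@name)
    }
  }

  if ("inventory" %in% stages) {
    inv <- if (!is.null(cfg$input$inventory)) {
      readInventory(cfg$input$inventory)
    } else {
      ic <- cfg$inventory %||% list()
      gf <- if (!is.null(ic$gene_freqs)) unlist(ic$gene_freqs)
            else defaultGeneFreqs()
      npp <- if (!is.null(ic$n_per_phylum)) unlist(ic$n_per_phylum)
             else c(synthetic_phylum = 250L)
      assoc <- if (!is.null(ic$associations)) {
        lapply(ic$associations, function(a)
          list(genes = unlist(a$genes), or = a$or))
      } else list(list(genes = c("narG", "nrfA"), or = 0.2))
      gen <- generateInventory(npp, gf, assoc,
                               ic$multi_copy_fraction %||% 0.05,
                               seed = cfg$seed)
      writeInventory(gen$inventory, art(pth("synthetic_inventory.tsv")))
      gen$inventory
    }
    calls <- classifyGenomes(inv)
    write.table(summarizeCohort(calls), art(pth("cohort_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    screen <- pairwiseGeneScreen(inv)
    write.table(screen, art(pth("cooccurrence.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pipeLog("inventory", nrow(inv), " genomes summarised; ",
            nrow(screen), " gene pairs screened")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nirkit")),
    seed = cfg$seed, stages = stages,
    config_hash = configHash(cfg[setdiff(names(cfg), "outdir")]),
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[sort(names(cfg))]), f)
  unname(tools::md5sum(f))
}
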