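# ---- end-to-end pipeline -----------------------------------------------------

#' Concatenate alignment partitions
#'
#' Columns of all partitions are joined; a taxon absent from a partition is
#' padded with `?` for that partition's sites and flagged. Partition
#' boundaries are recorded in the `"partitions"` attribute.
#'
#' @param alns list of [seq_alignment()] objects.
#' @return a [seq_alignment()] over the union of taxa, with attributes
#'   `"partitions"` (data frame: name, start, end) and `"padded"` (named
#'   list of padded taxa per partition).
#' @examples
#' a <- seq_alignment(c(x = "ACGT", y = "ACGA"))
#' b <- seq_alignment(c(x = "TT", y = "TC"))
#' ncol(concatenate_partitions(list(a, b)))  # 6
#' @export
concatenate_partitions <- function(alns) {
  stopifnot(length(alns) >= 1L, all(vapply(alns, inherits, logical(1),
                                           "seq_alignment")))
  if (length(alns) == 1L) return(alns[[1]])
  taxa <- sort(unique(unlist(lapply(alns, rownames))))
  nm <- names(alns)
  if (is.null(nm)) nm <- paste0("partition", seq_along(alns))
  parts <- list()
  padded <- list()
  pos <- 0L
  blocks <- lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    block <- matrix("?", length(taxa), ncol(a),
                    dimnames = list(taxa, NULL))
    block[rownames(a), ] <- unclass(a)
    miss <- setdiff(taxa, rownames(a))
    padded[[nm[i]]] <<- miss
    parts[[i]] <<- data.frame(name = nm[i], start = pos + 1L,
                              end = pos + ncol(a))
    pos <<- pos + ncol(a)
    block
  })
  out <- seq_alignment(do.call(cbind, blocks))
  attr(out, "partitions") <- do.call(rbind, parts)
  attr(out, "padded") <- padded
  out
}

#' Combine molecular and morphological data for parsimony
#'
#' Column-wise union treated uniformly by the parsimony engine; each column
#' keeps its own alphabet. Taxon sets must agree.
#'
#' @param aln a [seq_alignment()].
#' @param morph a [morph_matrix()] over the same taxa (may have 0 columns).
#' @return object of class `mixed_matrix` with elements `aln` and `morph`.
#' @export
combine_data <- function(aln, morph) {
  stopifnot(inherits(aln, "seq_alignment"), inherits(morph, "morph_matrix"))
  if (!setequal(rownames(aln), rownames(morph)))
    stop("alignment and morphology must cover the same taxa", call. = FALSE)
  structure(list(aln = aln, morph = morph), class = "mixed_matrix")
}

#' @export
print.mixed_matrix <- function(x, ...) {
  cat("Mixed matrix:", nrow(x$aln), "taxa;", ncol(x$aln),
      "molecular +", ncol(x$morph), "morphological columns\n")
  invisible(x)
}

.pipeline_defaults <- list(
  alignment = NULL, morphology = NULL, tree = NULL,
  distance_model = "k2p", groups = NULL,
  focal_group = NULL, origin_character = NULL, origin_state = NULL,
  bootstrap = 0, search = "nni", seed = 1,
  w_c = 1, w_p = 1, standardize = FALSE, out_dir = "patroclad_out")

#' Run the full analysis pipeline
#'
#' Orchestrates the analytic chain on file inputs: pairwise distances and
#' group means, a parsimony search with optional bootstrap (or a supplied
#' reference tree), clade diagnosis for a focal group, character-state
#' origin counting, and the patrocladistic analysis. Each stage is run
#' independently; a failing stage is recorded in the manifest and its
#' downstream stages are skipped, while earlier outputs are kept.
#'
#' @param config a named list or path to a YAML file. Recognized keys:
#'   `alignment` (FASTA/NEXUS path or vector of paths, concatenated),
#'   `morphology` (CSV/NEXUS path), `tree` (Newick path; when absent a
#'   parsimony search supplies the cladogram), `distance_model`
#'   (`"p"`/`"k2p"`), `groups` (named list of taxon vectors), `focal_group`
#'   (group name to test for monophyly), `origin_character` (index into the
#'   morphology columns), `origin_state`, `bootstrap` (replicate count; 0
#'   to skip), `search` (`"exhaustive"`/`"nni"`), `seed`, `w_c`, `w_p`,
#'   `standardize`, `out_dir`. Unknown keys are errors.
#' @return the run manifest (named list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(.pipeline_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "patroclad",
                   version = as.character(utils::packageVersion("patroclad")),
                   seed = cfg$seed, config = cfg, inputs = list(),
                   stages = list(), outputs = character(0))
  for (f in c(cfg$alignment, cfg$morphology, cfg$tree)) {
    if (file.exists(f)) manifest$inputs[[f]] <- unname(tools::md5sum(f))
  }
  emit <- function(path) manifest$outputs <<- c(manifest$outputs, path)
  stage <- function(name, deps_ok, fun) {
    if (!deps_ok) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(res))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      res
    }
  }
  out <- function(...) file.path(cfg$out_dir, paste0(...))

  aln <- stage("read_alignment", !is.null(cfg$alignment), function() {
    parts <- lapply(cfg$alignment, read_alignment)
    names(parts) <- basename(unlist(cfg$alignment))
    concatenate_partitions(parts)
  })
  morph <- stage("read_morphology", !is.null(cfg$morphology), function()
    read_morph_matrix(cfg$morphology))

  stage("distances", !is.null(aln), function() {
    dm <- pairwise_matrix(aln, model = cfg$distance_model)
    write_distance_matrix(dm, out("distances.csv"))
    emit(out("distances.csv"))
    if (!is.null(cfg$groups)) {
      gn <- names(cfg$groups)
      rows <- list()
      for (i in seq_along(gn)) for (j in seq(i, length(gn))) {
        v <- tryCatch({
          if (i == j) group_mean_distance(dm, cfg$groups[[i]])
          else group_mean_distance(dm, cfg$groups[[i]], cfg$groups[[j]])
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          group1 = gn[i], group2 = gn[j], mean_distance = v)
      }
      utils::write.csv(do.call(rbind, rows), out("group_means.csv"),
                       row.names = FALSE)
      emit(out("group_means.csv"))
    }
    dm
  })

  tree <- stage("tree", !is.null(cfg$tree) || !is.null(aln) ||
                  !is.null(morph), function() {
    if (!is.null(cfg$tree))
      return(parse_newick(paste(readLines(cfg$tree, warn = FALSE),
                                collapse = "")))
    dat <- if (!is.null(aln) && !is.null(morph)) combine_data(aln, morph)
    else if (!is.null(aln)) aln else morph
    set.seed(cfg$seed)
    res <- if (cfg$search == "exhaustive") exhaustive_search(dat)
    else nni_search(dat)
    tr <- if (length(res$trees) > 1L) consensus_tree(res$trees, "strict")
    else res$trees[[1]]
    writeLines(write_newick(tr), out("mp_tree.nwk"))
    emit(out("mp_tree.nwk"))
    tr
  })

  stage("bootstrap", cfg$bootstrap > 0 && (!is.null(aln) || !is.null(morph)),
        function() {
    dat <- if (!is.null(aln) && !is.null(morph)) combine_data(aln, morph)
    else if (!is.null(aln)) aln else morph
    bs <- bootstrap_support(dat, n_reps = cfg$bootstrap, seed = cfg$seed,
                            search = cfg$search)
    writeLines(write_newick(bs), out("bootstrap_consensus.nwk"))
    emit(out("bootstrap_consensus.nwk"))
    bs
  })

  stage("clades", !is.null(tree) && !is.null(cfg$focal_group), function() {
    focal <- cfg$groups[[cfg$focal_group]]
    if (is.null(focal)) stop("focal_group not found in groups")
    crep <- assess_monophyly(tree, focal)
    jsonlite::write_json(crep[c("verdict", "intruders", "missing")],
                         out("clade_report.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    emit(out("clade_report.json"))
    crep
  })

  stage("origins", !is.null(tree) && !is.null(morph) &&
          !is.null(cfg$origin_character) && !is.null(cfg$origin_state),
        function() {
    j <- cfg$origin_character
    col <- stats::setNames(as.character(unclass(morph)[, j]),
                           rownames(morph))
    orep <- min_state_origins(tree, col, as.character(cfg$origin_state))
    jsonlite::write_json(orep[c("origins", "branch_gains", "root_focal",
                                "length")],
                         out("origin_report.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    emit(out("origin_report.json"))
    orep
  })

  # morphology is the character source when configured; the alignment is the
  # fallback only when no morphology was requested at all
  patro_dat_ok <- !is.null(tree) &&
    (if (!is.null(cfg$morphology)) !is.null(morph) else !is.null(aln))
  stage("patrocladistics", patro_dat_ok, function() {
    dat <- if (!is.null(morph)) morph else aln
    dat <- .restrict_taxa(dat, tree$tip.label)
    pa <- patrocladistic_analysis(tree, dat, w_c = cfg$w_c, w_p = cfg$w_p,
                                  standardize = cfg$standardize)
    write_distance_matrix(pa$combined, out("combined_matrix.csv"))
    utils::write.csv(as.data.frame(pa$display),
                     out("cladistic_patristic_matrix.csv"))
    writeLines(write_newick(pa$patrocladogram$tree),
               out("patrocladogram.nwk"))
    emit(out("combined_matrix.csv"))
    emit(out("cladistic_patristic_matrix.csv"))
    emit(out("patrocladogram.nwk"))
    pa
  })

  for (p in manifest$outputs)
    manifest$inputs[[p]] <- unname(tools::md5sum(p))
  manifest_path <- out("manifest.json")
  jsonlite::write_json(
    list(tool = manifest$tool, version = manifest$version,
         seed = manifest$seed, stages = manifest$stages,
         outputs = manifest$outputs, checksums = manifest$inputs),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# subset a data object to given taxa
.restrict_taxa <- function(data, taxa) {
  if (inherits(data, "seq_alignment"))
    seq_alignment(unclass(data)[taxa, , drop = FALSE])
  else morph_matrix(unclass(data)[taxa, , drop = FALSE])
}
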