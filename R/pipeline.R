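#' Compute the full trait panel for one colony
#'
#' All fifteen headline traits (five morphological, ten network) plus the
#' three derived size-normalized variants used by the combined-scale
#' analyses: `G_eff_MST`, `R_eff_area`, `RT_eff_area`.
#'
#' @param net a root-attached [mycelial_network].
#' @param chunk_k,replicates,seed robustness-attack settings, see
#'   [robustness_traits()].
#' @param label optional colony label; `species`/`phylum` are taken from
#'   `net$metadata` when present.
#' @return one-row data.frame.
#' @export
compute_traits <- function(net, chunk_k = NULL, replicates = 100,
                           seed = 1L, label = NULL) {
  morph <- morphological_traits(net)
  netw <- network_traits(net)
  rob <- robustness_traits(net, chunk_k = chunk_k,
                           replicates = replicates, seed = seed)
  row <- as.data.frame(c(morph, netw, rob))
  row$scale_class <- net$scale_class
  if (!is.null(net$metadata$species)) row$species <- net$metadata$species
  if (!is.null(net$metadata$phylum)) row$phylum <- net$metadata$phylum
  if (!is.null(label)) row$colony <- label
  row
}

#' Trait table for a set of colonies
#'
#' @param nets list of root-attached [mycelial_network] objects.
#' @param ... passed to [compute_traits()].
#' @return data.frame, one row per colony.
#' @export
trait_table <- function(nets, ...) {
  do.call(rbind, lapply(seq_along(nets), function(i) {
    nm <- names(nets)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("colony", i)
    compute_traits(nets[[i]], label = nm, ...)
  }))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a batch of phenotype-preset colonies
#'
#' Grows `n_rep` colonies per requested preset phenotype with seeds
#' derived deterministically from `seed`, labelling each network's
#' metadata with its phenotype as "species" (and a two-level grouping of
#' presets as "phylum" stand-in so the partial-RDA plumbing is
#' exercised).
#'
#' @param phenotypes character vector of [preset_params()] names.
#' @param n_rep colonies per phenotype.
#' @param seed base RNG seed.
#' @return named list of networks.
#' @export
simulate_colonies <- function(phenotypes = c("guerrilla", "intermediate",
                                             "phalanx"),
                              n_rep = 3, seed = 1L) {
  nets <- list()
  for (ph in phenotypes) {
    for (r in seq_len(n_rep)) {
      s <- (seed * 1000L + match(ph, phenotypes) * 100L + r) %% .Machine$integer.max
      net <- grow_network(preset_params(ph, seed = s))
      net$metadata$species <- ph
      net$metadata$phylum <- if (ph == "guerrilla") "sparse" else "dense"
      nets[[paste(ph, r, sep = "_")]] <- net
    }
  }
  nets
}

#' Write / read a trait CSV
#'
#' The CSV carries a commented provenance header (tool version, seed).
#'
#' @param table trait data.frame.
#' @param path file path.
#' @param meta named character vector added to the header comment.
#' @return `path` (write) or the table (read).
#' @export
write_trait_csv <- function(table, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("myconet"))
  writeLines(c(sprintf("# myconet %s trait table", ver),
               sprintf("# %s=%s", names(meta), meta)), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Export RDA results as CSV tables
#'
#' Writes the variance partition (inertia and proportion per component),
#' the permutation test (Df, Variance, F, p), site scores, and trait
#' loadings.
#'
#' @param res an [rda_model()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisible vector of files written.
#' @export
export_rda <- function(res, dir = ".", prefix = "rda") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- res$fit
  f1 <- file.path(dir, paste0(prefix, "_variance_partition.csv"))
  write.csv(data.frame(component = names(fit$inertia),
                       inertia = as.numeric(fit$inertia),
                       proportion = as.numeric(fit$proportion)),
            f1, row.names = FALSE)
  f2 <- file.path(dir, paste0(prefix, "_test.csv"))
  write.csv(data.frame(
    term = c("constrained", "residual"),
    Df = c(fit$rank_x, fit$df_res),
    Variance = c(fit$inertia[["constrained"]],
                 fit$inertia[["unconstrained"]]),
    F = c(fit$pseudo_f, NA),
    p = c(res$test$p_value, NA)), f2, row.names = FALSE)
  f3 <- file.path(dir, paste0(prefix, "_site_scores.csv"))
  write.csv(as.data.frame(fit$sites), f3, row.names = TRUE)
  f4 <- file.path(dir, paste0(prefix, "_loadings.csv"))
  write.csv(as.data.frame(fit$loadings), f4, row.names = TRUE)
  invisible(c(f1, f2, f3, f4))
}

#' Export archetype results
#'
#' @param res an [archetype_analysis()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisible vector of files written.
#' @export
export_archetypes <- function(res, dir = ".", prefix = "pareto") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_archetypes.csv"))
  write.csv(res$nearest, f1, row.names = FALSE)
  f2 <- file.path(dir, paste0(prefix, "_scores.csv"))
  write.csv(as.data.frame(res$scores), f2, row.names = TRUE)
  f3 <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(k = res$k, t_ratio = res$t_ratio,
                            p_random = res$p_random, n_rand = res$n_rand,
                            seed = res$seed),
                       f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}

#' Load a pipeline configuration
#'
#' YAML key-value file; see `inst/cli/example_config.yaml` for the
#' recognized keys. CLI flags override config values.
#'
#' @param path YAML file.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run a pipeline subcommand
#'
#' Thin orchestration over the package's functions, used by the
#' `inst/cli/myconet.R` command-line script. Subcommands: `simulate`
#' (preset colonies to edge-list CSVs), `extract` (image to edge list),
#' `traits` (edge lists to trait CSV), `rda`, `pareto`, `all`
#' (simulate + traits + rda + pareto).
#'
#' @param command subcommand name.
#' @param config named list (see [load_config()]).
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(command = c("simulate", "extract", "traits",
                                     "rda", "pareto", "all"),
                         config = list()) {
  command <- match.arg(command)
  if (command == "extract") {
    if (is.null(config$image)) stop("extract: config needs 'image'")
    if (is.null(config$pixel_size)) {
      stop("extract: config needs 'pixel_size'")
    }
  }
  out <- config$out %||0% "myconet_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||0% 1L)
  artifacts <- list()
  if (command %in% c("simulate", "all")) {
    nets <- simulate_colonies(
      phenotypes = config$phenotypes %||0%
        c("guerrilla", "intermediate", "phalanx"),
      n_rep = config$n_rep %||0% 3, seed = seed)
    for (nm in names(nets)) {
      f <- file.path(out, paste0(nm, "_edges.csv"))
      write_network(nets[[nm]], f, "csv")
      artifacts[[nm]] <- f
    }
    if (command == "simulate") return(invisible(artifacts))
    tab <- trait_table(nets, replicates = config$replicates %||0% 25,
                       seed = seed)
  }
  if (command == "extract") {
    img <- load_image(config$image)
    params <- extraction_params(
      pixel_size = as.numeric(config$pixel_size),
      invert = isTRUE(config$invert))
    net <- extract_network(img, params)
    f <- file.path(out, "extracted_edges.csv")
    write_network(net, f, "csv")
    return(invisible(list(edges = f)))
  }
  if (command %in% c("traits", "rda", "pareto")) {
    if (!is.null(config$trait_csv)) {
      tab <- read_trait_csv(config$trait_csv)
    } else if (!is.null(config$edge_lists)) {
      nets <- lapply(config$edge_lists, function(f) {
        net <- load_network(f, scale_class = config$scale_class %||0% "micro")
        if (is.na(net$root_id)) {
          ctr <- colMeans(net$nodes[, c("x", "y")])
          d <- sqrt((net$nodes$x - ctr[1])^2 + (net$nodes$y - ctr[2])^2)
          net <- attach_root(net, ctr, net$nodes$id[which.min(d)])
        }
        net
      })
      tab <- trait_table(nets, replicates = config$replicates %||0% 25,
                         seed = seed)
    } else {
      stop(command, ": config needs 'trait_csv' or 'edge_lists'")
    }
  }
  if (command %in% c("traits", "all")) {
    f <- file.path(out, "traits.csv")
    write_trait_csv(tab, f, c(seed = seed))
    artifacts$traits <- f
    if (command == "traits") return(invisible(artifacts))
  }
  if (command %in% c("rda", "all")) {
    res <- rda_model(tab, config$rda_model %||0% "model3_all",
                     n_perm = config$n_perm %||0% 999, seed = seed)
    artifacts$rda <- export_rda(res, out)
    if (command == "rda") return(invisible(artifacts))
  }
  if (command %in% c("pareto", "all")) {
    Y <- standardize(select_traits(tab, "model3_all"))
    res <- archetype_analysis(Y, k = config$k %||0% 3,
                              n_rand = config$n_rand %||0% 1000,
                              seed = seed)
    artifacts$pareto <- export_archetypes(res, out)
  }
  invisible(artifacts)
}

#' Load a grayscale image from PNG or TIFF
#'
#' @param path image file.
#' @return numeric matrix in 0..1 (multi-channel images are averaged).
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package needed")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package needed")
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}
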