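# Pipeline orchestration: one configuration drives every stage
# (simulate -> superpose -> RMSD/RMSF -> cluster -> distances/H-bonds ->
# CVs/FEL -> DCCM -> energetics -> network/communities/paths), with a
# provenance manifest and deterministic, byte-stable TSV outputs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

matrix_to_tsv <- function(M, path, key_col = "key") {
  df <- data.frame(rownames(M), as.data.frame(unclass(M), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- key_col
  write_tsv(df, path)
}

#' Default pipeline configuration
#'
#' Mirrors the study's analysis settings (4.5 A contact cutoff, 75%
#' occupancy, natural-log edge weights, 3.5 A hydrogen-bond cutoff, gamma =
#' 0.00542 kcal/mol/A^2, b = 0.92 kcal/mol, 300 K landscapes) on top of the
#' default synthetic complex: a 20-residue receptor with two planted
#' correlation blocks, a planted high-correlation chain linking them, a
#' ligand and an LXXLL cofactor peptide.
#'
#' @param seed integer seed for every stochastic stage.
#' @param n_frames number of synthetic frames.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 7, n_frames = 500) {
  list(
    seed = seed,
    synthetic = list(
      n_receptor_residues = 20,
      first_resid = 580,
      include_ligand = TRUE,
      include_peptide = TRUE,
      n_frames = n_frames,
      per_residue_sigma = 0.5,
      rigid_jitter = c(0.5, 5),
      background = 0,
      blocks = list(list(members = 1:8, rho = 0.75),
                    list(members = 13:20, rho = 0.75)),
      chain = list(members = c(4, 6, 8, 10, 12, 14, 16), rho = 0.9)
    ),
    input = NULL,  # alternative: list(ensemble=, params=, reference=)
    selections = list(fit = "chain A and name CA",
                      calpha = "name CA",
                      receptor = "chain A",
                      partner = "chain B",
                      network_nodes = "chain A"),
    motif_chain = "B",
    distances = list(list(name = "D590_OD1__Rp2_NE", a = "A:590:OD1", b = "R+2:NE")),
    hbond_cutoff = 3.5,
    cvs = list(list(name = "pocket_A", a = "A:581:CA", b = "A:588:CA", c = "A:595:CA"),
               list(name = "pocket_B", a = "A:583:CA", b = "A:590:CA", c = "A:596:CA")),
    fel = list(bins = 50, temperature = 300),
    clustering = list(k = 3, seed = 11),
    network = list(cutoff = 4.5, min_occupancy = 0.75, exclusion = 1,
                   contact_mode = "heavy", log_base = exp(1), delta = 0.2),
    paths = list(source = "A:583", target = "A:595"),
    energetics = list(stride = 25, eps_in = 1.0, eps_solv = 80.0,
                      gamma = 0.00542, b = 0.92, probe = 1.4,
                      sasa_points = 240),
    stages = c("simulate", "superpose", "rmsd_rmsf", "cluster", "distances",
               "fel", "dccm", "energetics", "network")
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Values omitted from the file fall back to [default_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, override) {
    for (nm in names(override)) {
      if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
          !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_cfg(base[[nm]], override[[nm]])
      } else {
        base[[nm]] <- override[[nm]]
      }
    }
    base
  }
  merge_cfg(default_config(), user)
}

config_topology <- function(config) {
  if (!is.null(config$input)) {
    ens <- read_ensemble(config$input$ensemble)
    params <- read_params(config$input$params)
    list(topology = ens$topology, ensemble = ens, params = params, truth = NULL)
  } else {
    s <- config$synthetic
    toy <- build_toy_complex(s$n_receptor_residues,
                             include_ligand = isTRUE(s$include_ligand),
                             include_peptide = isTRUE(s$include_peptide),
                             first_resid = as.integer(s$first_resid))
    list(topology = toy$model, ensemble = NULL, params = toy$params, truth = NULL)
  }
}

#' Validate a pipeline configuration
#'
#' Resolves every selection, atom reference and collective variable against
#' the topology and checks all numeric ranges, aggregating every problem
#' into one human-readable error list (never failing on the first error
#' only).
#'
#' @param config configuration list (see [default_config()]).
#' @return list with `ok` (logical) and `errors` (character vector).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  top <- tryCatch(config_topology(config)$topology, error = function(e) {
    note(paste("topology:", conditionMessage(e))); NULL
  })
  num_check <- function(value, what, lo = -Inf, hi = Inf) {
    if (is.null(value) || !is.numeric(value) || value < lo || value > hi) {
      note(sprintf("%s out of range [%g, %g]: %s", what, lo, hi,
                   paste(value, collapse = ",")))
    }
  }
  num_check(config$network$min_occupancy, "network occupancy threshold", 0, 1)
  num_check(config$network$cutoff, "network contact cutoff", 1e-6, Inf)
  num_check(config$hbond_cutoff, "hydrogen-bond cutoff", 1e-6, Inf)
  num_check(config$fel$bins, "FEL bins", 2, Inf)
  num_check(config$fel$temperature, "temperature", 1e-6, Inf)
  num_check(config$clustering$k, "cluster count k", 1, Inf)
  num_check(config$energetics$stride, "energetics stride", 1, Inf)
  if (is.null(config$input)) {
    num_check(config$synthetic$n_frames, "n_frames", 2, Inf)
    num_check(config$synthetic$per_residue_sigma, "per_residue_sigma", 1e-9, Inf)
  }
  if (!is.null(top)) {
    motif <- tryCatch(
      if (!is.null(config$motif_chain)) motif_mapping(top, config$motif_chain) else NULL,
      error = function(e) { note(paste("motif:", conditionMessage(e))); NULL })
    for (nm in names(config$selections)) {
      tryCatch(resolve_selection(top, config$selections[[nm]]),
               error = function(e) note(sprintf("selection '%s': %s", nm,
                                                conditionMessage(e))))
    }
    for (d in config$distances) {
      for (ref in c(d$a, d$b)) {
        tryCatch(resolve_atom_ref(top, ref, motif),
                 error = function(e) note(sprintf("distance '%s': %s", d$name,
                                                  conditionMessage(e))))
      }
    }
    for (cv in config$cvs) {
      for (ref in c(cv$a, cv$b, cv$c)) {
        tryCatch(resolve_atom_ref(top, ref, motif),
                 error = function(e) note(sprintf("CV '%s': %s", cv$name,
                                                  conditionMessage(e))))
      }
    }
  }
  list(ok = length(errors) == 0, errors = errors)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage against one configuration, writing TSV/JSON
#' outputs and a provenance manifest under `out_dir`. Reruns with the same
#' configuration and seed reproduce byte-identical TSV outputs; finished
#' stages are resumed from an on-disk cache unless `force = TRUE`. A stage
#' failure halts the run with a manifest recording the completed stages.
#'
#' @param config configuration list (see [default_config()], [read_run_config()]).
#' @param out_dir output directory.
#' @param force recompute even when cached stage results exist.
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  v <- validate_config(config)
  if (!v$ok) {
    stop("invalid configuration:\n  - ", paste(v$errors, collapse = "\n  - "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest <- list(config_hash = hash, seed = config$seed,
                   replica_mode = "single", stages = list())
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }
  enabled <- function(stage) stage %in% config$stages
  run_stage <- function(name, compute) {
    cache_file <- file.path(cache_dir, paste0(name, ".rds"))
    if (!force && file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (identical(cached$hash, hash) && all(file.exists(cached$outputs))) {
        message("stage ", name, ": cached")
        manifest$stages[[name]] <<- list(outputs = cached$outputs, cached = TRUE)
        return(cached$value)
      }
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(compute(), error = function(e) {
      manifest$stages[[name]] <<- list(error = conditionMessage(e))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    message(sprintf("stage %s: %.2f s", name, proc.time()[["elapsed"]] - t0))
    saveRDS(list(hash = hash, value = res$value, outputs = res$outputs),
            cache_file)
    manifest$stages[[name]] <<- list(outputs = res$outputs, cached = FALSE)
    res$value
  }
  path_of <- function(...) file.path(out_dir, ...)

  ## stage: simulate (or load)
  sim <- run_stage("simulate", function() {
    base <- config_topology(config)
    if (!is.null(base$ensemble)) {
      return(list(value = list(ensemble = base$ensemble, params = base$params,
                               truth = NULL, topology = base$topology),
                  outputs = character(0)))
    }
    s <- config$synthetic
    res <- residue_table(base$topology)
    blocks <- lapply(s$blocks, function(b) list(members = as.integer(b$members),
                                                rho = b$rho))
    chain <- if (!is.null(s$chain)) list(members = as.integer(s$chain$members),
                                         rho = s$chain$rho)
    corr <- plant_correlation(nrow(res), blocks = blocks, chain = chain,
                              background = s$background)
    samp <- sample_ensemble(base$topology, corr,
                            per_residue_sigma = s$per_residue_sigma,
                            n_frames = s$n_frames, seed = config$seed,
                            rigid_jitter = as.numeric(s$rigid_jitter))
    paths <- write_fixture(samp$ensemble, samp$truth, base$params,
                           path_of("fixture"))
    list(value = list(ensemble = samp$ensemble, params = base$params,
                      truth = samp$truth, topology = base$topology),
         outputs = unlist(paths))
  })

  ## stage: superpose
  ens <- run_stage("superpose", function() {
    list(value = superpose(sim$ensemble, fit_sel = config$selections$fit),
         outputs = character(0))
  })
  motif <- if (!is.null(config$motif_chain) &&
               config$motif_chain %in% sim$topology$atoms$chain) {
    motif_mapping(sim$topology, config$motif_chain)
  }

  if (enabled("rmsd_rmsf")) {
    run_stage("rmsd_rmsf", function() {
      rmsd <- rmsd_series(ens, sel = config$selections$fit)
      rmsf <- rmsf_profile(ens, sel = config$selections$fit)
      o1 <- write_tsv(data.frame(frame = seq_along(rmsd), rmsd_A = rmsd),
                      path_of("rmsd.tsv"))
      o2 <- write_tsv(data.frame(residue = rmsf$key, rmsf_A = rmsf$rmsf),
                      path_of("rmsf.tsv"))
      list(value = NULL, outputs = c(o1, o2))
    })
  }

  if (enabled("cluster")) {
    run_stage("cluster", function() {
      cl <- kmeans_frames(ens, sel = config$selections$calpha,
                          k = config$clustering$k, seed = config$clustering$seed)
      o1 <- write_tsv(data.frame(frame = seq_along(cl$assignments),
                                 cluster = cl$assignments),
                      path_of("cluster_assignments.tsv"))
      outs <- o1
      for (j in seq_len(cl$k)) {
        rp <- path_of(sprintf("representative_cluster%d.pdb", j))
        write_structure(representative_structure(cl, ens, j), rp)
        outs <- c(outs, rp)
      }
      elbow <- kmeans_elbow(ens, sel = config$selections$calpha,
                            k_range = 1:min(8, n_frames(ens)),
                            seed = config$clustering$seed)
      outs <- c(outs, write_tsv(elbow, path_of("cluster_elbow.tsv")))
      list(value = cl, outputs = outs)
    })
  }

  if (enabled("distances")) {
    run_stage("distances", function() {
      outs <- character(0)
      series <- data.frame(frame = seq_len(n_frames(ens)))
      occ <- data.frame(name = character(0), occupancy = numeric(0))
      for (d in config$distances) {
        s <- distance_series(ens, d$a, d$b, motif)
        series[[d$name]] <- s
        occ <- rbind(occ, data.frame(name = d$name,
                                     occupancy = hbond_occupancy(s, config$hbond_cutoff)))
        dens <- distance_density(s)
        outs <- c(outs, write_tsv(dens, path_of(sprintf("density_%s.tsv", d$name))))
      }
      outs <- c(write_tsv(series, path_of("distances.tsv")),
                write_tsv(occ, path_of("hbond_occupancy.tsv")), outs)
      list(value = NULL, outputs = outs)
    })
  }

  if (enabled("fel")) {
    run_stage("fel", function() {
      cv1 <- triangle_area_series(ens, with(config$cvs[[1]], triangle_cv(a, b, c, name)), motif)
      cv2 <- triangle_area_series(ens, with(config$cvs[[2]], triangle_cv(a, b, c, name)), motif)
      fel <- fel_2d(cv1, cv2, bins = config$fel$bins,
                    temperature = config$fel$temperature)
      o1 <- write_tsv(data.frame(frame = seq_along(cv1),
                                 cv1 = cv1, cv2 = cv2), path_of("cv_series.tsv"))
      G <- fel$free_energy
      dimnames(G) <- list(sprintf("bin%d", seq_len(nrow(G))),
                          sprintf("bin%d", seq_len(ncol(G))))
      o2 <- matrix_to_tsv(G, path_of("fel_free_energy.tsv"), key_col = "cv1_bin")
      meta <- list(cv1 = config$cvs[[1]]$name, cv2 = config$cvs[[2]]$name,
                   cv1_edges = fel$cv1_edges, cv2_edges = fel$cv2_edges,
                   temperature = fel$temperature,
                   masked_bins = sum(fel$counts == 0))
      o3 <- path_of("fel_meta.json")
      jsonlite::write_json(meta, o3, auto_unbox = TRUE, digits = NA)
      list(value = fel, outputs = c(o1, o2, o3))
    })
  }

  dccm_mat <- NULL
  if (enabled("dccm") || enabled("network")) {
    dccm_mat <- run_stage("dccm", function() {
      M <- dccm(ens, sel = config$selections$calpha)
      o <- matrix_to_tsv(M, path_of("dccm.tsv"), key_col = "residue")
      list(value = M, outputs = o)
    })
  }

  if (enabled("energetics") && !is.null(sim$params) &&
      !is.null(config$selections$partner) &&
      any(sim$topology$atoms$chain == "B")) {
    run_stage("energetics", function() {
      e <- config$energetics
      dec <- binding_decomposition(ens, config$selections$receptor,
                                   config$selections$partner, sim$params,
                                   stride = e$stride, eps_in = e$eps_in,
                                   eps_solv = e$eps_solv, gamma = e$gamma,
                                   b = e$b, probe = e$probe,
                                   sasa_points = e$sasa_points)
      o1 <- write_tsv(dec$totals, path_of("energy_totals.tsv"))
      o2 <- write_tsv(dec$per_residue, path_of("energy_per_residue.tsv"))
      list(value = NULL, outputs = c(o1, o2))
    })
  }

  if (enabled("network")) {
    run_stage("network", function() {
      nw <- config$network
      adj <- contact_occupancy(ens, config$selections$network_nodes,
                               cutoff = nw$cutoff,
                               min_occupancy = nw$min_occupancy,
                               contact_mode = nw$contact_mode,
                               exclusion = nw$exclusion)
      net <- weight_edges(adj, dccm_mat, log_base = nw$log_base)
      o1 <- write_tsv(net$edges[, c("node_a", "node_b", "occupancy", "abs_c",
                                    "weight")], path_of("network_edges.tsv"))
      part <- detect_communities(net)
      o2 <- write_tsv(data.frame(residue = names(part$membership),
                                 community = as.integer(part$membership)),
                      path_of("communities.tsv"))
      conn <- intercommunity_connectivity(net, part)
      o3 <- if (length(conn) > 0) {
        dimnames(conn) <- list(sprintf("c%d", seq_len(nrow(conn))),
                               sprintf("c%d", seq_len(ncol(conn))))
        matrix_to_tsv(conn, path_of("intercommunity.tsv"), key_col = "community")
      } else character(0)
      paths_out <- data.frame(rank = integer(0), length_raw = numeric(0),
                              length_x100 = integer(0), n_residues = integer(0),
                              residues = character(0))
      if (!is.null(config$paths)) {
        sub <- suboptimal_paths(net, config$paths$source, config$paths$target,
                                delta = nw$delta)
        if (length(sub) > 0) {
          paths_out <- data.frame(
            rank = seq_along(sub),
            length_raw = vapply(sub, function(p) p$length, numeric(1)),
            length_x100 = vapply(sub, function(p) p$length_x100, integer(1)),
            n_residues = vapply(sub, function(p) p$n_residues, integer(1)),
            residues = vapply(sub, function(p) paste(p$residues, collapse = ","),
                              character(1)))
        }
      }
      o4 <- write_tsv(paths_out, path_of("paths.tsv"))
      list(value = list(network = net, partition = part),
           outputs = c(o1, o2, o3, o4))
    })
  }
  finish()
}
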