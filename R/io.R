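# Readers and writers for the text formats the pipeline consumes and
# produces: GRO and multi-model PDB structures, energy tables, umbrella
# windows, density/cluster/band CSVs and the JSON run configuration.
# All coordinates are nm internally; PDB files are Angstrom on disk.

# chain <-> residue-name encoding used in GRO files (which have no chain
# field): protomer A = PRA, protomer B = PRB, lipid = LIP
.chain_to_resname <- c(A = "PRA", B = "PRB", L = "LIP")
.resname_to_chain <- stats::setNames(names(.chain_to_resname), .chain_to_resname)

#' Bead table of one ensemble frame
#'
#' @param ens a `daft_ensemble`
#' @param replicate replicate index
#' @param frame stored-frame index (1-based; see `ens$times`)
#' @return data.frame chain, resid, resname, atom, x, y, z (nm)
#' @export
ensemble_structure <- function(ens, replicate = 1L, frame = length(ens$times)) {
  tpl <- ens$template
  one <- function(chain, cols) {
    p <- ens$pose[frame, replicate, cols]
    b <- beads_lab(tpl, p[1], p[2], p[3])
    data.frame(chain = chain, resid = tpl$residue_index,
               resname = .chain_to_resname[[chain]], atom = "BB",
               x = b[, 1], y = b[, 2], z = b[, 3])
  }
  rbind(one("A", c("xA", "yA", "phiA")), one("B", c("xB", "yB", "phiB")))
}

#' Write a structure to a GRO file
#'
#' @param df bead data.frame (chain, resid, resname, atom, x, y, z in nm)
#' @param path output file
#' @param box box vector (nm)
#' @param title title line
#' @return `path`, invisibly
#' @export
write_gro <- function(df, path, box = c(13, 13, 9), title = "dimerscope frame") {
  lines <- c(title, format(nrow(df)))
  atomno <- seq_len(nrow(df)) %% 1e5
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            df$resid %% 1e5, df$resname, df$atom, atomno,
                            df$x, df$y, df$z))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2],
                            if (length(box) > 2) box[3] else 9))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file
#'
#' @param path file
#' @return bead data.frame (nm) with `box` attribute; chains recovered from
#'   the residue-name encoding
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("read_gro: truncated file (< 3 lines): ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("read_gro: bad atom count at line 2")
  if (length(lines) < 2L + nat + 1L)
    stop(sprintf("read_gro: truncated file, expected atom lines up to line %d",
                 2L + nat))
  al <- lines[3:(2 + nat)]
  parse_num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("read_gro: malformed %s at line %d", what, ln[bad[1]]))
    v
  }
  ln <- 3:(2 + nat)
  df <- data.frame(
    resid = as.integer(parse_num(substr(al, 1, 5), "residue number", ln)),
    resname = trimws(substr(al, 6, 10)),
    atom = trimws(substr(al, 11, 15)),
    x = parse_num(substr(al, 21, 28), "x coordinate", ln),
    y = parse_num(substr(al, 29, 36), "y coordinate", ln),
    z = parse_num(substr(al, 37, 44), "z coordinate", ln))
  df$chain <- unname(.resname_to_chain[df$resname])
  df <- df[, c("chain", "resid", "resname", "atom", "x", "y", "z")]
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + nat + 1L]), "\\s+")[[1]]))
  attr(df, "box") <- box
  df
}

#' Write a (multi-model) PDB file
#'
#' Coordinates are converted nm -> Angstrom. A list of data.frames becomes
#' one MODEL per element; per-model times (us) are stored in REMARK 250
#' records.
#'
#' @param frames a bead data.frame or list thereof
#' @param path output file
#' @param times optional per-model times (us)
#' @return `path`, invisibly
#' @export
write_pdb <- function(frames, path, times = NULL) {
  if (is.data.frame(frames)) frames <- list(frames)
  out <- character(0)
  for (m in seq_along(frames)) {
    df <- frames[[m]]
    out <- c(out, sprintf("MODEL     %4d", m))
    if (!is.null(times))
      out <- c(out, sprintf("REMARK 250 TIME_US %.6f", times[m]))
    out <- c(out, sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(df)) %% 1e5, substr(df$atom, 1, 4),
      substr(df$resname, 1, 3), df$chain, df$resid %% 1e4,
      df$x * 10, df$y * 10, df$z * 10))
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a (multi-model) PDB file
#'
#' @param path file
#' @return list of bead data.frames (coordinates nm), with `times`
#'   attribute when REMARK 250 TIME_US records are present
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  models <- list(); times <- numeric(0)
  cur <- list(); cur_time <- NA_real_
  flush <- function() {
    if (length(cur)) {
      models[[length(models) + 1L]] <<- do.call(rbind, cur)
      times[length(times) + 1L] <<- cur_time
      cur <<- list(); cur_time <<- NA_real_
    }
  }
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (startsWith(l, "MODEL")) flush()
    else if (startsWith(l, "REMARK 250 TIME_US"))
      cur_time <- as.numeric(sub("REMARK 250 TIME_US", "", l))
    else if (startsWith(l, "ATOM") || startsWith(l, "HETATM")) {
      if (nchar(l) < 54) stop(sprintf("read_pdb: truncated ATOM record at line %d", i))
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                           substr(l, 47, 54))))
      if (anyNA(xyz))
        stop(sprintf("read_pdb: malformed coordinates at line %d", i))
      cur[[length(cur) + 1L]] <- data.frame(
        chain = substr(l, 22, 22),
        resid = as.integer(substr(l, 23, 26)),
        resname = trimws(substr(l, 18, 21)),
        atom = trimws(substr(l, 13, 16)),
        x = xyz[1] / 10, y = xyz[2] / 10, z = xyz[3] / 10)
    } else if (startsWith(l, "ENDMDL")) flush()
  }
  flush()
  if (!length(models)) stop("read_pdb: no ATOM records in ", path)
  attr(models, "times") <- times
  models
}

#' Read a structure file (GRO or PDB), dispatching on the extension
#'
#' Coordinates are returned in nm regardless of the source dialect.
#'
#' @param path file ending in .gro or .pdb
#' @return bead data.frame (GRO) or list of frames (PDB)
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro(path),
         pdb = read_pdb(path),
         stop("read_structure: unsupported extension .", ext))
}

#' Write a structure file (GRO or PDB), dispatching on the extension
#' @param df bead data.frame (or list of frames for PDB)
#' @param path file ending in .gro or .pdb
#' @param ... passed to the format writer
#' @return `path`, invisibly
#' @export
write_structure <- function(df, path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = write_gro(df, path, ...),
         pdb = write_pdb(df, path, ...),
         stop("write_structure: unsupported extension .", ext))
}

#' Orientation frames from structure files
#'
#' Computes (beta, chi, COM distance, minimum bead distance) directly from
#' bead coordinates of chains A and B, matching the pose-based path: the
#' reference vector is the in-plane difference of the template's two
#' reference beads within each chain.
#'
#' @param frames list of bead data.frames (e.g. from [read_pdb()])
#' @param template the `protomer_template` the beads follow
#' @param box optional periodic box (nm)
#' @param times frame times (default: `times` attribute, else 1..n)
#' @param replicate replicate id for the output table
#' @return orientation-frame data.frame
#' @export
structure_orientation_frames <- function(frames, template, box = NULL,
                                         times = NULL, replicate = 1L) {
  if (is.null(times)) times <- attr(frames, "times")
  if (is.null(times) || anyNA(times)) times <- seq_along(frames)
  rv <- template$refvec_beads
  rows <- lapply(seq_along(frames), function(fi) {
    df <- frames[[fi]]
    A <- as.matrix(df[df$chain == "A", c("x", "y", "z")])
    B <- as.matrix(df[df$chain == "B", c("x", "y", "z")])
    if (!nrow(A) || !nrow(B))
      stop("structure_orientation_frames: need chains A and B")
    comA <- colMeans(A); comB <- colMeans(B)
    dx <- comB[1] - comA[1]; dy <- comB[2] - comA[2]
    if (!is.null(box)) { dx <- .min_image(dx, box[1]); dy <- .min_image(dy, box[2]) }
    vA <- A[rv[1], 1:2] - A[rv[2], 1:2]
    vB <- B[rv[1], 1:2] - B[rv[2], 1:2]
    psi <- .plane_angle(dx, dy)
    ddx <- outer(A[, 1], B[, 1], "-"); ddy <- outer(A[, 2], B[, 2], "-")
    if (!is.null(box)) { ddx <- .min_image(ddx, box[1]); ddy <- .min_image(ddy, box[2]) }
    ddz <- outer(A[, 3], B[, 3], "-")
    data.frame(replicate = replicate, time = times[fi],
               beta = wrap_angle(psi - .plane_angle(vA[1], vA[2])),
               chi = wrap_angle(psi + 180 - .plane_angle(vB[1], vB[2])),
               com_distance = sqrt(dx^2 + dy^2),
               min_bead_distance = sqrt(min(ddx^2 + ddy^2 + ddz^2)))
  })
  do.call(rbind, rows)
}

#' Write / read interaction-energy tables
#'
#' CSV with columns replicate, time_us, E_interaction_kJmol.
#'
#' @param tab energy table data.frame
#' @param path CSV file
#' @return `path` / data.frame
#' @export
write_energy_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("replicate", "time_us", "E_interaction_kJmol")
  if (!all(need %in% names(df)))
    stop("read_energy_table: expected columns ", paste(need, collapse = ", "))
  df
}

#' Write / read umbrella windows
#'
#' One two-column whitespace-separated file (time, xi in nm) per window,
#' plus a manifest CSV (file, center_nm, k_kJmol_nm2, n_samples).
#'
#' @param windows list of `umbrella_window`s
#' @param dir output directory
#' @return manifest path / list of windows
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.dat", seq_along(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    utils::write.table(data.frame(time = w$time, xi = w$xi),
                       file.path(dir, files[i]),
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(
    file = files,
    center_nm = vapply(windows, `[[`, numeric(1), "center"),
    k_kJmol_nm2 = vapply(windows, `[[`, numeric(1), "k"),
    n_samples = vapply(windows, function(w) length(w$xi), numeric(1)))
  mp <- file.path(dir, "windows_manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname write_umbrella_windows
#' @param manifest path to a windows manifest CSV
#' @export
read_umbrella_windows <- function(manifest) {
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.table(file.path(dir, man$file[i]))
    umbrella_window(man$center_nm[i], man$k_kJmol_nm2[i], d[[2]], d[[1]])
  })
}

#' Write a toroidal density grid as CSV
#'
#' Matrix layout: header row of chi bin centers, first column beta bin
#' centers, cells = enrichment.
#'
#' @param density an `orientation_density`
#' @param path CSV file
#' @return `path`, invisibly
#' @export
write_density_csv <- function(density, path) {
  m <- density$enrichment
  df <- data.frame(beta_center_deg = density$centers, m, check.names = FALSE)
  names(df)[-1] <- sprintf("chi_%g_deg", density$centers)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster set as CSV
#' @param clusters a `cluster_set`
#' @param path CSV file
#' @return `path`, invisibly
#' @export
write_clusters_csv <- function(clusters, path) {
  utils::write.csv(as.data.frame(clusters), path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All pipeline-stage parameters with their package defaults; the basis
#' against which configuration files are validated (unknown keys are
#' rejected).
#'
#' @return named list
#' @export
run_config_defaults <- function() {
  list(seed = 1L, n_replicates = 64L, duration = 2.0,
       times = c(0, 0.5, 1.0, 1.5, 2.0),
       dimer_cutoff = 0.6, grid_n = 72L, density_bandwidth = 5,
       min_enrichment = 2, min_population = 3,
       contact_cutoff = 0.5, contact_frames = 5L, contact_window = 0.1,
       bundle_fraction_threshold = 0.5, bundle_persistence = 2L,
       out_dir = "dimerscope_out", log_level = "info")
}

#' Read and validate a JSON run configuration
#'
#' @param path JSON file whose keys mirror [run_config_defaults()]
#' @return validated configuration list (defaults filled in)
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("read_run_config: unknown configuration keys: ",
         paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' Run the full synthetic-ensemble analysis pipeline
#'
#' Generates the default planted ensemble, builds orientation densities at
#' the configured time slices, detects and pairs clusters at the final
#' time, computes the ensemble contact map, the bundle-domain screen and
#' the energy vigintile bands, writes every product as CSV under
#' `out_dir`, and writes a JSON manifest listing outputs, parameters,
#' package version and file checksums. Deterministic for a given seed.
#'
#' @param config configuration list (see [run_config_defaults()]) or a path
#'   to a JSON configuration
#' @return (invisibly) list of results and the manifest
#' @export
run_pipeline <- function(config = run_config_defaults()) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("run_pipeline: unknown configuration keys: ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  outputs <- character(0)
  results <- list()

  tpl <- stage("template", build_protomer_template())
  ens <- stage("simulate", generate_daft_ensemble(
    tpl, default_interaction_map(),
    ensemble_config(n_replicates = cfg$n_replicates, duration = cfg$duration,
                    seed = cfg$seed)))
  frames <- stage("orientation_frames", orientation_frames(ens, times = cfg$times))
  results$frames <- frames

  results$densities <- list()
  for (t in cfg$times) {
    d <- stage("orientation_density",
               orientation_density(frames, at_time = t,
                                   dimer_cutoff = cfg$dimer_cutoff,
                                   grid_n = cfg$grid_n,
                                   bandwidth = cfg$density_bandwidth))
    f <- file.path(out_dir, sprintf("density_t%.1fus.csv", t))
    write_density_csv(d, f); outputs <- c(outputs, f)
    results$densities[[sprintf("%.1f", t)]] <- d
  }
  dfinal <- results$densities[[sprintf("%.1f", max(cfg$times))]]
  clusters <- stage("detect_clusters",
                    detect_clusters(dfinal, min_enrichment = cfg$min_enrichment,
                                    min_population = cfg$min_population))
  f <- file.path(out_dir, "clusters.csv")
  write_clusters_csv(clusters, f); outputs <- c(outputs, f)
  results$clusters <- clusters

  cmap <- stage("contacts", residue_contact_map(
    ens, cutoff = cfg$contact_cutoff, n_frames = cfg$contact_frames,
    window = cfg$contact_window))
  f <- file.path(out_dir, "contact_map.csv")
  utils::write.csv(as.data.frame(unclass(cmap)), f); outputs <- c(outputs, f)
  fc <- filter_contacts(cmap)
  f <- file.path(out_dir, "contacts_sparse.csv")
  utils::write.csv(fc, f, row.names = FALSE); outputs <- c(outputs, f)
  results$contact_map <- cmap

  screen <- stage("bundle_screen", bundle_screen(
    ens, bundle_fraction_threshold = cfg$bundle_fraction_threshold,
    persistence = cfg$bundle_persistence, cutoff = cfg$contact_cutoff))
  f <- file.path(out_dir, "bundle_screen.csv")
  utils::write.csv(as.data.frame(screen), f, row.names = FALSE)
  outputs <- c(outputs, f)
  results$bundle_screen <- screen

  bands <- stage("convergence", vigintile_bands(energy_table(ens)))
  f <- file.path(out_dir, "energy_vigintiles.csv")
  utils::write.csv(as.data.frame(bands), f, row.names = FALSE)
  outputs <- c(outputs, f)
  results$bands <- bands

  et <- energy_table(ens)
  f <- file.path(out_dir, "energies.csv")
  write_energy_table(et, f); outputs <- c(outputs, f)

  manifest <- list(
    package = "dimerscope",
    version = as.character(utils::packageVersion("dimerscope")),
    parameters = cfg,
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs))),
    n_clusters_merged = count_merged_clusters(clusters),
    bundle_screen_count = attr(screen, "count"),
    bundle_screen_percentage = attr(screen, "percentage"))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
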