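# Component-table ingestion and publication-style report assembly.

# canonical row names of a binding free-energy component table
.component_rows <- c("dE_vdw", "dE_c", "gamma.dMSA", "dG_R", "dG_bind")
.component_rows_optional <- c("dG_exp", "ddG_bind")

#' Parse a "mean±err" cell
#'
#' Accepts ASCII and typographic variants: `-33.35±0.19`, `−33.35+/-0.19`,
#' or a bare number (error 0).
#'
#' @param cell character scalar
#' @return list with `mean` and `err`
#' @export
parse_pm_cell <- function(cell) {
  s <- gsub("−", "-", trimws(cell))   # Unicode minus
  s <- gsub("\\+/-", "±", s)
  parts <- strsplit(s, "±")[[1]]
  num <- suppressWarnings(as.numeric(trimws(parts)))
  if (!length(num) || length(num) > 2 || anyNA(num) || !nzchar(s))
    stop("malformed mean±err cell: '", cell, "'")
  list(mean = num[1], err = if (length(num) == 2) num[2] else 0)
}

format_pm_cell <- function(mean, err) {
  sprintf("%.2f±%.2f", mean, err)
}

#' Read a binding free-energy components table
#'
#' TSV with first column `energy` holding the row labels (`dE_vdw`, `dE_c`,
#' `gamma.dMSA`, `dG_R`, `dG_bind`; optional `dG_exp`, `ddG_bind`) and one
#' column per system; cells are `mean±err` strings. Unknown row labels are
#' an error; malformed cells are reported with their row and column.
#'
#' @param path file path
#' @return named list (one entry per system column) of data.frames with
#'   columns `row`, `mean`, `err`
#' @export
ingest_components_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  if (names(tab)[1] != "energy")
    stop("components table must have first column 'energy'")
  bad <- setdiff(tab$energy, c(.component_rows, .component_rows_optional))
  if (length(bad))
    stop("unknown component row(s): ", paste(bad, collapse = ", "))
  systems <- names(tab)[-1]
  out <- list()
  for (s in systems) {
    cells <- lapply(seq_len(nrow(tab)), function(i) {
      tryCatch(parse_pm_cell(tab[[s]][i]),
               error = function(e) stop("row '", tab$energy[i],
                                        "', column '", s, "': ",
                                        conditionMessage(e)))
    })
    out[[s]] <- data.frame(row = tab$energy,
                           mean = vapply(cells, `[[`, 0, "mean"),
                           err = vapply(cells, `[[`, 0, "err"),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Write a components table (round-trips with [ingest_components_table()])
#'
#' @param components named list of data.frames (`row`, `mean`, `err`) or of
#'   [energy_components()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_components_table <- function(components, path) {
  components <- lapply(components, function(x) {
    if (inherits(x, "energy_components")) components_to_rows(x) else x
  })
  rows <- components[[1]]$row
  tab <- data.frame(energy = rows, stringsAsFactors = FALSE)
  for (s in names(components)) {
    m <- components[[s]]
    tab[[s]] <- format_pm_cell(m$mean[match(rows, m$row)],
                               m$err[match(rows, m$row)])
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

components_to_rows <- function(ec) {
  data.frame(
    row = .component_rows,
    mean = c(ec$mean["e_vdw"], ec$mean["e_coulomb"],
             ec$mean["gamma_msa_term"], ec$mean["g_reaction"], ec$dg_bind),
    err = c(ec$sem["e_vdw"], ec$sem["e_coulomb"], ec$sem["gamma_msa_term"],
            ec$sem["g_reaction"], ec$dg_bind_sem),
    stringsAsFactors = FALSE)
}

table_value <- function(components, system, row) {
  m <- components[[system]]
  if (is.null(m)) stop("no such system column: ", system)
  v <- m$mean[m$row == row]
  if (!length(v)) stop("system '", system, "' has no row '", row, "'")
  v
}

#' Signed difference of one component between two systems
#'
#' Emitted as an explicit `minuend - subtrahend` with both named, since
#' prose sign conventions for "increase/decrease" statements are ambiguous.
#'
#' @param components output of [ingest_components_table()]
#' @param row component row name (e.g. `dE_c`)
#' @param minuend,subtrahend system column names
#' @return one-row data.frame (`comparison`, `row`, `value`)
#' @export
components_difference <- function(components, row, minuend, subtrahend) {
  v <- table_value(components, minuend, row) -
    table_value(components, subtrahend, row)
  data.frame(comparison = paste0(minuend, " - ", subtrahend), row = row,
             value = v, stringsAsFactors = FALSE)
}

#' Recombine a component table column through the SIE function
#'
#' Applies the SIE linear combination to the four component rows of one
#' system column; useful to validate a table's own dG_bind row.
#'
#' @param components output of [ingest_components_table()]
#' @param system system column name
#' @param coefficients a [sie_coefficients()] object
#' @return kcal/mol
#' @export
sie_from_table <- function(components, system,
                           coefficients = sie_coefficients()) {
  sie_combine(e_coulomb = table_value(components, system, "dE_c"),
              e_vdw = table_value(components, system, "dE_vdw"),
              g_reaction = table_value(components, system, "dG_R"),
              gamma_msa_term = table_value(components, system, "gamma.dMSA"),
              coefficients = coefficients)
}

#' Wild-vs-mutant ddG from a component table
#'
#' ddG = dG_bind(mutant) - dG_bind(wild), recomputed from the table's dG
#' rows; a printed `ddG_bind` row that disagrees is flagged, not
#' reproduced.
#'
#' @param components output of [ingest_components_table()]
#' @param wild,mutant system column names
#' @param tol discrepancy tolerance, kcal/mol
#' @return list with `ddg` and `flags`
#' @export
ddg_from_table <- function(components, wild, mutant, tol = 0.005) {
  ddg <- table_value(components, mutant, "dG_bind") -
    table_value(components, wild, "dG_bind")
  flags <- character()
  m <- components[[mutant]]
  if ("ddG_bind" %in% m$row) {
    printed <- m$mean[m$row == "ddG_bind"]
    if (abs(printed - ddg) > tol)
      flags <- sprintf(
        "printed ddG_bind %.2f inconsistent with dG columns (%.2f - %.2f = %.2f); using recomputed",
        printed, table_value(components, mutant, "dG_bind"),
        table_value(components, wild, "dG_bind"), ddg)
  }
  list(ddg = ddg, flags = flags)
}

# ---------------------------------------------------------------------------
# Config + pipeline

#' Read a `key: value` configuration file
#'
#' One `key: value` pair per line; `#` starts a comment; repeated keys keep
#' the last value. Values stay strings; consumers coerce.
#'
#' @param path file path
#' @return named list
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("bad config line: ", ln)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

config_get <- function(config, key, default = NULL, as = identity) {
  if (is.null(config[[key]])) default else as(config[[key]])
}

#' Frame indices of the equilibrium window
#'
#' By default the last third of the trajectory is analysed (the analogue of
#' keeping the last 20 ns of a 60 ns run); the fraction is a config knob.
#'
#' @param traj an `md_trajectory` (or a frame count)
#' @param fraction trailing fraction of frames to keep
#' @return integer frame indices
#' @export
equilibrium_frames <- function(traj, fraction = 1 / 3) {
  F_ <- if (is.numeric(traj)) traj else n_frames(traj)
  keep <- max(1L, as.integer(floor(F_ * fraction)))
  seq(F_ - keep + 1L, F_)
}

log_stage <- function(con, stage, inputs = character(), ...) {
  extras <- list(...)
  hash <- if (length(inputs))
    paste(paste0(basename(inputs), "=",
                 substr(unname(tools::md5sum(inputs)), 1, 8)),
          collapse = ",")
  else ""
  kv <- paste(names(extras), vapply(extras, function(x)
    paste(format(x), collapse = ";"), ""), sep = "=", collapse = " ")
  writeLines(sprintf("stage=%s inputs=[%s] %s", stage, hash, kv), con)
}

#' Run the analysis pipeline from a configuration
#'
#' Config keys: `structure` (PDB), `trajectory` (multi-model PDB),
#' `parameters` (TSV), `stages` (comma list from dccm, rmsf, sie, hbonds,
#' polar, contacts, alascan), `output_dir`, `seed`, plus stage knobs
#' (`equilibrium_fraction`, `snapshot_stride`, `grid_spacing`, `margin`,
#' `hbond_dmax`, `hbond_angle_min`, `hbond_occupancy_min`, `contact_cutoff`,
#' `bin_width`, `polar_residues` (comma-separated ids), `mutate`
#' ("chain:res_id"), `regions` ("name=a-b" comma list)). All named inputs
#' are checked before any computation starts; outputs are deterministic
#' TSV/JSON files plus a `pipeline.log` with one structured line per stage.
#'
#' @param config path to a config file, or a named list
#' @return named list of written file paths, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_config(config)
  stages <- strsplit(config_get(config, "stages", "dccm,rmsf"), ",")[[1]]
  stages <- trimws(stages)
  out_dir <- config_get(config, "output_dir", "mdsie_out")
  for (key in c("structure", "trajectory", "parameters")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("missing input before computation: ", key, " = ", p)
  }
  if (is.null(config$structure)) stop("config needs 'structure'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config_get(config, "seed", 1L, as.integer)
  set.seed(seed)
  log_con <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(log_con))

  system <- read_pdb(config$structure)
  if (!is.null(config$parameters))
    system <- assign_parameters(system,
                                read_parameter_table(config$parameters))
  traj <- if (!is.null(config$trajectory))
    read_trajectory(config$trajectory, system)
  else trajectory(array(coords(system), dim = c(1, nrow(system$atoms), 3)))
  eqf <- config_get(config, "equilibrium_fraction", 1 / 3, as.numeric)
  eq_idx <- equilibrium_frames(traj, eqf)
  eq_traj <- trajectory(traj$frames[eq_idx, , , drop = FALSE],
                        traj$frame_interval)
  ca <- select_atoms(system, name = "CA", group = "protein")
  ca_labels <- system$atoms$res_id[ca]
  written <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written[[name]] <<- path
  }
  inputs <- unlist(config[c("structure", "trajectory", "parameters")])

  for (stage in stages) {
    switch(stage,
      dccm = {
        m <- dccm(eq_traj, selection = ca, labels = as.character(ca_labels))
        emit("dccm.tsv", function(p) write_dccm(m, p))
        emit("dccm.json", function(p)
          jsonlite::write_json(list(labels = attr(m, "labels"),
                                    values = unclass(m)), p, digits = NA))
        log_stage(log_con, "dccm", inputs, seed = seed,
                  frames = n_frames(eq_traj), atoms = length(ca))
      },
      rmsf = {
        r <- rmsf(eq_traj, selection = ca)
        tab <- data.frame(res_id = ca_labels, rmsf = as.numeric(r))
        emit("rmsf.tsv", function(p)
          write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
        reg_str <- config_get(config, "regions")
        if (!is.null(reg_str)) {
          kv <- strsplit(strsplit(reg_str, ",")[[1]], "=")
          spec <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
          rs <- region_summary(setNames(as.numeric(r), ca_labels),
                               region_spec(spec))
          emit("rmsf_regions.tsv", function(p)
            write.table(rs, p, sep = "\t", quote = FALSE, row.names = FALSE))
        }
        log_stage(log_con, "rmsf", inputs, seed = seed,
                  frames = n_frames(eq_traj))
      },
      sie = {
        stride <- config_get(config, "snapshot_stride", 1L, as.integer)
        opts <- sie_options(
          grid_spacing = config_get(config, "grid_spacing", 0.5, as.numeric),
          margin = config_get(config, "margin", 10, as.numeric))
        ec <- sie_trajectory(eq_traj, system, snapshot_stride = stride,
                             options = opts)
        emit("sie_components.tsv", function(p)
          write_components_table(list(system = ec), p))
        emit("sie_components.json", function(p)
          jsonlite::write_json(list(mean = as.list(ec$mean),
                                    sem = as.list(ec$sem),
                                    dg_bind = ec$dg_bind,
                                    n_snapshots = ec$n_snapshots),
                               p, auto_unbox = TRUE, digits = NA))
        log_stage(log_con, "sie", inputs, seed = seed,
                  snapshots = ec$n_snapshots,
                  grid_spacing = opts$grid_spacing)
      },
      hbonds = {
        hb <- detect_hbonds(
          eq_traj, system,
          d_max = config_get(config, "hbond_dmax", 3.5, as.numeric),
          angle_min = config_get(config, "hbond_angle_min", 120, as.numeric),
          occupancy_min = config_get(config, "hbond_occupancy_min", 0.5,
                                     as.numeric))
        bw <- config_get(config, "bin_width", 0.05, as.numeric)
        en <- lapply(hb, hbond_energy_mean)
        tab <- data.frame(
          bond = vapply(hb, `[[`, "", "label"),
          occupancy = vapply(hb, `[[`, 0, "occupancy"),
          mean = vapply(en, `[[`, 0, "mean"),
          sd = vapply(en, `[[`, 0, "sd"))
        emit("hbonds.tsv", function(p)
          write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
        for (k in seq_along(hb)) {
          h <- distance_distribution(hb[[k]], bw)
          emit(sprintf("hbond_hist_%d.tsv", k), function(p)
            write.table(h, p, sep = "\t", quote = FALSE, row.names = FALSE))
        }
        emit("hbond_total.json", function(p)
          jsonlite::write_json(list(total = complex_hbond_total(tab$mean)),
                               p, auto_unbox = TRUE, digits = NA))
        log_stage(log_con, "hbonds", inputs, seed = seed, bonds = nrow(tab))
      },
      polar = {
        ids <- config_get(config, "polar_residues", as = function(x)
          as.integer(strsplit(x, ",")[[1]]))
        if (is.null(ids)) stop("polar stage needs 'polar_residues'")
        pe <- lapply(ids, function(i)
          residue_polar_energy(eq_traj, system, i))
        tab <- data.frame(res_id = ids,
                          mean = vapply(pe, `[[`, 0, "mean"),
                          sem = vapply(pe, `[[`, 0, "sem"))
        tab <- rbind(tab, data.frame(res_id = NA, mean =
          polar_total(tab$mean), sem = NA))
        emit("polar.tsv", function(p)
          write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
        log_stage(log_con, "polar", inputs, seed = seed,
                  residues = length(ids))
      },
      contacts = {
        hc <- hydrophobic_contacts(
          eq_traj, system,
          cutoff = config_get(config, "contact_cutoff", 3.9, as.numeric))
        emit("contacts.tsv", function(p)
          write.table(hc$occupancy, p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
        log_stage(log_con, "contacts", inputs, seed = seed)
      },
      alascan = {
        mut_str <- config_get(config, "mutate")
        if (is.null(mut_str)) stop("alascan stage needs 'mutate'")
        parts <- strsplit(mut_str, ":")[[1]]
        spec <- mutation_spec(parts[1], as.integer(parts[2]))
        params <- read_parameter_table(config$parameters)
        mut_sys <- mutate_to_alanine(system, spec, params)
        mut_traj <- mutate_trajectory(eq_traj, system, spec)
        stride <- config_get(config, "snapshot_stride", 1L, as.integer)
        opts <- sie_options(
          grid_spacing = config_get(config, "grid_spacing", 0.5, as.numeric),
          margin = config_get(config, "margin", 10, as.numeric))
        wild <- sie_trajectory(eq_traj, system, snapshot_stride = stride,
                               options = opts)
        mut <- sie_trajectory(mut_traj, mut_sys, snapshot_stride = stride,
                              options = opts)
        rep <- alanine_scan_report(wild, mut)
        emit("alascan_mutant.pdb", function(p) write_pdb(mut_sys, p))
        emit("alascan.tsv", function(p)
          write.table(rep$components, p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
        emit("alascan.json", function(p)
          jsonlite::write_json(list(ddg = rep$ddg, flags = rep$flags),
                               p, auto_unbox = TRUE, digits = NA))
        log_stage(log_con, "alascan", inputs, seed = seed,
                  mutate = mut_str, ddg = rep$ddg)
      },
      stop("unknown stage: ", stage)
    )
  }
  invisible(written)
}
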