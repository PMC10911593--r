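#' Load a scenario description
#'
#' Scenarios are YAML files bundling a model choice, its rate parameters,
#' the habitat block, the initial populations, and an experiment driver
#' with its controls.  The schema is strict: unknown keys are rejected, a
#' two-compartment habitat block must carry exactly one of \code{K}
#' (capacities) or \code{d} (death rates), and the migration block must be
#' either explicit (\code{m} scalar or \code{matrix}) or geometric
#' (\code{kernel} plus \code{distances}), not both.  When both an explicit
#' matrix and geometry are present the explicit matrix wins with a warning.
#'
#' The scenarios shipped with the package (see [list_fixtures()] /
#' [scenario_fixture()]) reproduce each printed parameter set of the
#' published experiments and double as schema documentation.
#'
#' @param path path to a YAML scenario file.
#' @return A validated object of class \code{"wb_scenario"}: the raw
#'   blocks plus resolved \code{p} (parameter object), \code{net}
#'   (two-compartment models), \code{M} (migration matrix), \code{kernel}
#'   and \code{state0} where applicable.
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("model", "note", "params", "habitats", "migration",
               "initial", "grid", "experiment", "kernel")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         " in ", path)
  model <- raw$model
  if (is.null(model) || !model %in% c("model1", "model2", "pde", "kernel"))
    stop("scenario 'model' must be one of model1, model2, pde, kernel")
  sc <- raw
  class(sc) <- "wb_scenario"
  if (model == "kernel") {
    sc$kernel <- resolve_kernel(raw$kernel)
    return(sc)
  }
  if (model %in% c("model1", "pde")) {
    pb <- raw$params
    need <- c("b_I", "b_U", "delta_I", "delta_U")
    if (!all(need %in% names(pb)))
      stop("model1 'params' must name ", paste(need, collapse = ", "))
    sc$p <- model1_params(pb$b_I, pb$b_U, pb$delta_I, pb$delta_U,
                          d = if (is.null(pb$d)) NA_real_ else pb$d)
  }
  if (model == "model1") {
    hb <- raw$habitats
    if (is.null(hb) || (is.null(hb$K) == is.null(hb$d)))
      stop("model1 'habitats' must carry exactly one of 'K' or 'd'")
    M <- resolve_migration(raw$migration,
                           n = length(if (!is.null(hb$K)) hb$K else hb$d))
    sc$M <- M
    sc$net <- habitat_network(M = M, K = hb$K, d = hb$d, p = sc$p)
    if (!is.null(raw$initial))
      sc$state0 <- c(as.numeric(raw$initial$x0), as.numeric(raw$initial$y0))
  } else if (model == "model2") {
    pb <- raw$params
    sc$p <- model2_params(pb$b_f, pb$b_m, pb$sigma, pb$phi_u, pb$phi_w,
                          pb$v_u, pb$v_w, pb$psi, pb$mu_a, pb$mu_fu,
                          pb$mu_fw, pb$mu_mu, pb$mu_mw, pb$K)
    if (!is.null(raw$initial)) {
      blocks <- lapply(raw$initial, as.numeric)
      if (!all(lengths(blocks) == 9L))
        stop("model2 'initial' habitat blocks must each have 9 entries (",
             paste(model2_compartments(), collapse = ", "), ")")
      sc$state0 <- unlist(blocks, use.names = FALSE)
    }
    if (!is.null(raw$migration))
      sc$M <- resolve_migration(raw$migration,
                                n = length(raw$initial %||% list(1, 2)))
  } else if (model == "pde") {
    gb <- raw$grid %||% list()
    sc$grid <- pde_grid(extent = gb$extent %||% c(-50, 150),
                        n = gb$nodes %||% 400, D = gb$D %||% 1,
                        bc = gb$bc %||% "reflect")
  }
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_kernel <- function(kb) {
  if (is.null(kb)) stop("missing 'kernel' block")
  kernel_spec(family = kb$family, xi = kb$xi, sigma = kb$sigma,
              t = kb$t, q = kb$q,
              ms_convention = kb$ms_convention %||% "table")
}

resolve_migration <- function(mb, n) {
  if (is.null(mb)) return(matrix(0, n, n))
  explicit <- !is.null(mb$m) || !is.null(mb$matrix)
  geometric <- !is.null(mb$kernel) || !is.null(mb$distances)
  if (explicit && geometric) {
    warning("migration block carries both an explicit coefficient and ",
            "geometry; the explicit value wins", call. = FALSE)
    geometric <- FALSE
  }
  if (!explicit && !geometric)
    stop("migration block must give 'm'/'matrix' or 'kernel'+'distances'")
  if (explicit) {
    if (!is.null(mb$matrix)) {
      M <- do.call(rbind, mb$matrix)
    } else {
      if (n != 2L) stop("scalar 'm' shorthand requires exactly 2 habitats")
      M <- matrix(c(0, mb$m, mb$m, 0), 2, 2)
    }
  } else {
    k <- resolve_kernel(mb$kernel)
    dist <- mb$distances
    if (!is.null(mb$positions)) dist <- NULL
    if (is.list(dist)) dist <- do.call(rbind, dist)
    M <- migration_matrix(k, dist %||% as.numeric(mb$positions))
  }
  M
}

#' List the scenario fixtures shipped with the package
#'
#' @return character vector of fixture names accepted by
#'   [scenario_fixture()].
#' @export
list_fixtures <- function() {
  dir <- system.file("extdata", "scenarios", package = "wolbanet")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load a named scenario fixture
#'
#' @param name a fixture name from [list_fixtures()].
#' @return a \code{"wb_scenario"}, see [load_scenario()].
#' @examples
#' sc <- scenario_fixture("fig5_basin")
#' sc$net
#' @export
scenario_fixture <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "wolbanet")
  if (path == "")
    stop("unknown fixture '", name, "'; see list_fixtures()")
  load_scenario(path)
}

#' Run the experiment a scenario describes
#'
#' Dispatches on the scenario's model and experiment driver:
#' \code{run} (integrate and classify each habitat), \code{release}
#' ([minimal_release()]), \code{basin} ([basin_boundary()]), \code{sweep}
#' ([migration_sweep()] or [model2_migration_sweep()]), \code{migration}
#' (kernel scenarios: [migration_rate()] over the listed distances), and
#' \code{pde} ([solve_pde()] plus outcome summary).
#'
#' @param sc a \code{"wb_scenario"} from [load_scenario()] or
#'   [scenario_fixture()].
#' @param ... overrides passed to the underlying driver.
#' @return the driver's result; for \code{run}, a list with the
#'   simulation, the terminal state and the per-habitat outcome table.
#' @export
run_scenario <- function(sc, ...) {
  stopifnot(inherits(sc, "wb_scenario"))
  ex <- sc$experiment %||% list(driver = "run")
  driver <- ex$driver %||% "run"
  ctl <- ex$controls %||% list()
  switch(paste(sc$model, driver, sep = "."),
    "kernel.migration" = {
      data.frame(distance = as.numeric(ctl$distances),
                 m = migration_rate(sc$kernel, as.numeric(ctl$distances)))
    },
    "model1.run" = {
      sim <- simulate_model1(sc$state0[seq_len(sc$net$N)],
                             sc$state0[sc$net$N + seq_len(sc$net$N)],
                             sc$net, sc$p,
                             times = ctl$horizon %||% 2000, ...)
      ss <- steady_state(sim)
      list(sim = sim, state = ss$state, converged = ss$converged,
           outcome = classify_outcome(ss$state, sc$net, sc$p))
    },
    "model1.release" = {
      minimal_release(sc$net, sc$p, habitat = ctl$habitat %||% 1L,
                      horizon = ctl$horizon %||% 4000, ...)
    },
    "model1.basin" = {
      basin_boundary(sc$net, sc$p,
                     x_A_grid = as.numeric(ctl$x_A_grid),
                     horizon = ctl$horizon %||% 4000, ...)
    },
    "model1.sweep" = {
      migration_sweep(sc$p, d = sc$net$d,
                      m_grid = as.numeric(ctl$m_grid),
                      x0 = sc$state0[1:2], y0 = sc$state0[3:4],
                      horizon = ctl$horizon %||% 6000, ...)
    },
    "model2.run" = {
      sim <- simulate_model2(sc$state0, sc$p, M = sc$M,
                             times = ctl$horizon %||% 2500, ...)
      ss <- steady_state(sim)
      list(sim = sim, state = ss$state, converged = ss$converged,
           outcome = classify_outcome(ss$state, p = sc$p))
    },
    "model2.sweep" = {
      model2_migration_sweep(sc$p, sc$state0,
                             m_grid = as.numeric(ctl$m_grid),
                             horizon = ctl$horizon %||% 2500, ...)
    },
    "model2.capacity_map" = {
      model2_capacity_map(sc$p, sc$state0,
                          m_grid = as.numeric(ctl$m_grid),
                          ratio_grid = as.numeric(ctl$ratio_grid),
                          horizon = ctl$horizon %||% 2500, ...)
    },
    "model2.release_map" = {
      model2_release_map(sc$p, sc$state0,
                         release_grid = as.numeric(ctl$release_grid),
                         m_grid = as.numeric(ctl$m_grid),
                         horizon = ctl$horizon %||% 2500, ...)
    },
    "pde.run" = {
      amp <- ctl$x_amplitude %||% 40
      sol <- solve_pde(sc$grid, sc$p,
                       x0 = function(s) amp * exp(-s^2),
                       y0 = ctl$y_level %||% 200,
                       times = seq(0, ctl$horizon %||% 150,
                                   length.out = ctl$snapshots %||% 40), ...)
      sol
    },
    stop("no driver '", driver, "' for model '", sc$model, "'"))
}

#' Write experiment results with a provenance header
#'
#' Writes a data frame as CSV preceded by commented header lines recording
#' the package version and scenario note, and mirrors the payload as JSON
#' next to it.  Data rows are deterministic, so re-running a fixture
#' reproduces them byte for byte.
#'
#' @param records a data frame of results.
#' @param path output CSV path (the JSON mirror replaces the extension).
#' @param note free-text provenance line (e.g. the scenario note).
#' @return invisibly, the paths written.
#' @export
write_results <- function(records, path, note = "") {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  writeLines(c(
    paste0("# wolbanet ", as.character(utils::packageVersion("wolbanet"))),
    paste0("# ", note)), con)
  utils::write.csv(records, con, row.names = FALSE)
  close(con)
  jpath <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(records, jpath, digits = NA, dataframe = "columns")
  invisible(c(csv = path, json = jpath))
}
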