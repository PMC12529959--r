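## Serialization: network round-trip as YAML, trajectory and sweep CSV
## output with a metadata sidecar.

#' Write / read a reaction network as YAML
#'
#' The schema stores, per reaction: id, forward rate constant \code{kf},
#' equilibrium constant \code{K} (absent for irreversible reactions), kind,
#' implicit-water stoichiometry and the reactant/product maps; plus the
#' buffer table and temperature. A re-imported network is identical in
#' constants and stoichiometry.
#'
#' @param network a \code{micp_network}.
#' @param path output file.
#' @return \code{write_network} returns \code{path} invisibly;
#'   \code{read_network} a \code{micp_network}.
#' @export
write_network <- function(network, path) {
  rx <- lapply(network$reactions, function(r) {
    out <- list(id = r$id, kind = r$kind, kf = r$kf,
                reactants = as.list(r$reactants),
                products = as.list(r$products), water = r$water)
    if (!is.na(r$K)) out$K <- r$K
    out
  })
  yaml::write_yaml(list(
    temperature = network$temperature,
    od = network$od,
    kf_R8 = network$kf_R8,
    buffers = if (nrow(network$buffers))
      lapply(seq_len(nrow(network$buffers)), function(i)
        as.list(network$buffers[i, c("name", "Ka", "total")]))
      else list(),
    reactions = rx), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- yaml::read_yaml(path)
  buf <- if (length(x$buffers)) {
    df <- do.call(rbind, lapply(x$buffers, as.data.frame))
    extra <- df$name == "Qx"
    bs <- buffer_set(totals = {
      t7 <- rep(0, 7)
      m <- match(df$name[!extra], names(.micp$buffer_Ka))
      t7[m] <- df$total[!extra]
      t7
    }, enabled = any(!extra),
    extra_total = if (any(extra)) df$total[extra] else 0,
    extra_pKa = if (any(extra)) -log10(df$Ka[extra]) else 10)
    bs
  } else buffer_set(enabled = FALSE)
  default_network(buffers = buf, temperature = x$temperature, od = x$od,
                  kf_R8 = x$kf_R8)
}

#' Write a trajectory as CSV with a metadata sidecar
#'
#' Full double precision, fixed column order: \code{time_s}, one column per
#' species (M), \code{pH}, \code{trapped_co2_M},
#' \code{co2_headspace_volfrac}. The sidecar YAML echoes the scenario and
#' integrator statistics.
#'
#' @param traj a \code{micp_trajectory}.
#' @param path CSV path.
#' @param meta_path sidecar path (default: \code{path} with \code{.meta.yml}).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             meta_path = paste0(path, ".meta.yml")) {
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  sc <- traj$scenario
  yaml::write_yaml(list(
    scenario = list(label = sc$label, urea_M = sc$urea, ca_M = sc$ca,
                    co2_volfrac = sc$co2_fraction, pH = sc$pH,
                    clamp = as.list(sc$clamp),
                    buffers_enabled = nrow(sc$buffers) > 0,
                    temperature_K = sc$temperature, pressure_atm = sc$pressure,
                    v_liq_L = sc$v_liq, v_gas_L = sc$v_gas,
                    duration_h = sc$duration_h),
    integrator = list(steps = unname(traj$diagnostics$istate[2]),
                      rhs_evals = unname(traj$diagnostics$istate[3]),
                      jacobian_evals = unname(traj$diagnostics$istate[4])),
    constants_source = "rate/equilibrium constant table of the model"),
    meta_path)
  invisible(path)
}

#' Write an equilibrium sweep as tidy CSV
#'
#' One row per grid cell (\code{urea_M, ca_M, co2_volfrac, buffers, pH,
#' trapped_M, caco3_M}); the argmax summary goes to a companion file.
#'
#' @param sweep a \code{micp_sweep}.
#' @param path CSV path.
#' @param argmax_path companion path (default \code{path} with
#'   \code{.argmax.csv}).
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(sweep, path,
                        argmax_path = paste0(path, ".argmax.csv")) {
  utils::write.csv(format(as.data.frame(sweep), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(attr(sweep, "argmax"), digits = 17, trim = TRUE),
                   argmax_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
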