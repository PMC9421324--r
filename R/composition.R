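#' Mean scattering length density of a lipid composition (F0)
#'
#' Computes the zeroth Fourier coefficient of the unit-cell SLD profile from
#' the chemical composition: the molar-ratio-weighted sum of coherent
#' scattering lengths divided by the corresponding sum of molecular volumes.
#' Each lipid carries `waters_per_lipid` hydration water molecules of the
#' stated D2O fraction (the hydration convention used for lamellar skin-lipid
#' models).
#'
#' @param composition Data frame with columns `species`, `formula`
#'   (chemical formula, `D` for deuterium), `molar_ratio` and optionally
#'   `density` (g/cm^3; default 1.0 per species).
#' @param waters_per_lipid Hydration waters per lipid molecule (default 1).
#' @param frac_d2o D2O percentage of the hydration water (default 8, the
#'   null-contrast point).
#' @return F0 in 1e-6 / Angstrom^2.
#' @export
#' @examples
#' comp <- data.frame(species = "FFA24", formula = "C24H48O2",
#'                    molar_ratio = 1, density = 1.0)
#' compute_F0(comp, waters_per_lipid = 0)
compute_F0 <- function(composition, waters_per_lipid = 1, frac_d2o = 8) {
  stopifnot(is.data.frame(composition),
            all(c("species", "formula", "molar_ratio") %in% names(composition)))
  if (any(composition$molar_ratio <= 0)) stop("molar ratios must be positive")
  dens <- if ("density" %in% names(composition)) composition$density else
    rep(1.0, nrow(composition))
  b_sum <- 0
  v_sum <- 0
  for (i in seq_len(nrow(composition))) {
    ms <- molecular_scattering(composition$formula[i], dens[i])
    r <- composition$molar_ratio[i]
    b_sum <- b_sum + r * ms$b_fm
    v_sum <- v_sum + r * ms$volume_A3
  }
  if (waters_per_lipid > 0) {
    f <- frac_d2o / 100
    w_d <- molecular_scattering("D2O", 1.107)
    w_h <- molecular_scattering("H2O", 0.997)
    n_w <- waters_per_lipid * sum(composition$molar_ratio)
    b_sum <- b_sum + n_w * (f * w_d$b_fm + (1 - f) * w_h$b_fm)
    v_sum <- v_sum + n_w * (f * w_d$volume_A3 + (1 - f) * w_h$volume_A3)
  }
  b_sum * 1e-5 / v_sum * 1e6
}

#' Hydrocarbon-chain inventory of the LPP lipid models
#'
#' Per-chain carbon bookkeeping for the five-component LPP model
#' (CER EOS : CER NS : CER NP : CHOL : FFA C24 = 0.4 : 0.3 : 0.3 : 1 : 1).
#' CER EOS contributes three chains (C30 acyl, C18 ester-linked linoleate,
#' C18 sphingosine); CER NS and CER NP contribute a C24 acyl plus a C18
#' sphingoid chain; FFA24 a single C24 chain. Cholesterol is a fused-ring
#' sterol, not a methylene chain, and is excluded from the chain inventory.
#'
#' @param model Which sample the deuteration pattern describes. One of
#'   `"LPP:prot"`, `"LPP:NSd47"`, `"LPP:NPd47"`, `"LPP:NSd7"`,
#'   `"LPP:NSd47:DFFA24"`, `"LPP:NPd47:DFFA24"`, `"LPP:NSd47:NPd47:DFFA24"`.
#' @return Data frame with columns `species`, `chain`, `carbons`,
#'   `molar_ratio`, `deuterated`.
#' @export
lpp_chain_inventory <- function(model = "LPP:prot") {
  chains <- data.frame(
    species = c("CER EOS", "CER EOS", "CER EOS",
                "CER NS", "CER NS", "CER NP", "CER NP", "FFA24"),
    chain = c("acyl_C30", "linoleate_C18", "sphingosine_C18",
              "acyl_C24", "sphingosine_C18", "acyl_C24",
              "phytosphingosine_C18", "chain_C24"),
    carbons = c(30, 18, 18, 24, 18, 24, 18, 24),
    molar_ratio = c(0.4, 0.4, 0.4, 0.3, 0.3, 0.3, 0.3, 1),
    stringsAsFactors = FALSE
  )
  deut <- switch(model,
    "LPP:prot" = character(0),
    "LPP:NSd47" = "CER NS/acyl_C24",
    "LPP:NPd47" = "CER NP/acyl_C24",
    "LPP:NSd7" = "CER NS/sphingosine_C18",   # terminal d7 only
    "LPP:NSd47:DFFA24" = c("CER NS/acyl_C24", "FFA24/chain_C24"),
    "LPP:NPd47:DFFA24" = c("CER NP/acyl_C24", "FFA24/chain_C24"),
    "LPP:NSd47:NPd47:DFFA24" =
      c("CER NS/acyl_C24", "CER NP/acyl_C24", "FFA24/chain_C24"),
    stop("unknown lipid model: ", model)
  )
  chains$deuterated <- paste(chains$species, chains$chain, sep = "/") %in% deut
  chains
}

#' Share of a chain among protiated chain carbons
#'
#' Fraction of the protiated hydrocarbon-chain carbon pool contributed by a
#' named chain, weighted by molar ratio. Used e.g. to express the liquid
#' linoleate chain of CER EOS as a share of the protiated chains remaining in
#' the triple-deuterated model.
#'
#' @param chains Chain inventory as from [lpp_chain_inventory()].
#' @param chain_name Chain to express as a share (matched against the
#'   `chain` column).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' inv <- lpp_chain_inventory("LPP:NSd47:NPd47:DFFA24")
#' protiated_chain_share(inv, "linoleate_C18")  # about 0.19
protiated_chain_share <- function(chains, chain_name) {
  stopifnot(all(c("chain", "carbons", "molar_ratio", "deuterated") %in%
                  names(chains)))
  prot <- chains[!chains$deuterated, , drop = FALSE]
  if (nrow(prot) == 0) stop("no protiated chains in inventory")
  pool <- sum(prot$carbons * prot$molar_ratio)
  share <- sum(prot$carbons[prot$chain == chain_name] *
                 prot$molar_ratio[prot$chain == chain_name])
  share / pool
}

#' Chain extents and label positions from C-C bond counts
#'
#' All-trans chain geometry: extent = bond count x C-C bond length
#' (0.125 nm). For an n-carbon acyl chain the bond count defaults to n - 1;
#' an explicit bond count overrides it (e.g. the sphingosine chain extends
#' over 15 C-C bonds beyond the head group). The predicted position of a
#' terminal label is the head-group position plus the chain extent.
#'
#' @param carbons Carbon count of the chain (used as `carbons - 1` bonds when
#'   `bonds` is `NULL`).
#' @param bonds Explicit C-C bond count (overrides `carbons`).
#' @param headgroup_position_nm Optional head-group distance from the
#'   unit-cell centre; when given, the predicted terminal position is
#'   returned as well.
#' @param cc_bond_length_nm C-C bond length (default 0.125 nm).
#' @return List with `bonds`, `chain_length_nm` and (when a head-group
#'   position is supplied) `predicted_position_nm`.
#' @export
#' @examples
#' predict_chain_positions(carbons = 24)$chain_length_nm          # 2.875
#' predict_chain_positions(bonds = 15)$chain_length_nm            # 1.875
#' predict_chain_positions(bonds = 15, headgroup_position_nm = 2.2)
predict_chain_positions <- function(carbons = NULL, bonds = NULL,
                                    headgroup_position_nm = NULL,
                                    cc_bond_length_nm = 0.125) {
  stopifnot(cc_bond_length_nm > 0)
  if (is.null(bonds)) {
    stopifnot(!is.null(carbons), carbons >= 2)
    bonds <- carbons - 1
  }
  if (bonds < 1) stop("bond count must be >= 1")
  out <- list(bonds = bonds, chain_length_nm = bonds * cc_bond_length_nm)
  if (!is.null(headgroup_position_nm)) {
    out$predicted_position_nm <- headgroup_position_nm + out$chain_length_nm
  }
  out
}
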