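# shared fixtures, all built in code

# a labels volume with a centered cubic tumor of the given edge (in voxels)
make_cube_labels <- function(n = 12, tumor_edge = 2) {
  labels <- array(TISSUE_LABELS[["fat"]], c(n, n, n))
  lo <- (n - tumor_edge) %/% 2 + 1
  hi <- lo + tumor_edge - 1
  labels[lo:hi, lo:hi, lo:hi] <- TISSUE_LABELS[["tumor"]]
  labels
}

# a uniform perfusion map on a lattice (no vessels unless present in labels)
make_uniform_map <- function(lattice, ktrans = 0.2, ve = 0.4, vp = 0.02) {
  shp <- lattice$shape
  perfusion_map(array(ktrans, shp), array(ve, shp), array(vp, shp), lattice)
}

# a small, fast case for engine tests: ellipsoid phantom + short regimen
make_test_case <- function(seed = 3, diameter = 10, dox_dose = 110,
                           n_doses = 4, surgery_gap = 21,
                           sensitivity = c(doxorubicin = 1)) {
  ph <- generate_phantom(phantom_spec(diameter = diameter, seed = seed))
  adm <- data.frame(drug = "doxorubicin", dose = dox_dose,
                    day = seq(0, by = 14, length.out = n_doses))
  reg <- regimen(adm, surgery_day = max(adm$day) + surgery_gap)
  case_record("test", 50, subtype = "TNBC", sensitivity = sensitivity,
              lattice = ph$lattice, perfusion = ph$perfusion,
              density = ph$density, regimen = reg)
}

fast_config <- function(...) sim_config(mechanics = "bookkeeping", ...)
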