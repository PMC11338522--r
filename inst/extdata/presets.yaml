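# Versioned simulation presets. Each preset resolves to a complete parameter
# set for scene generation, rendering and quantification; the scale factors
# encode the programmed effect sizes that the recovery suite re-estimates.
version: 1
presets:

  # Widefield/confocal-style intensity experiments: a condition pair in which
  # the test group's signal is reduced by a programmed factor, either through
  # the photon budget (puromycin labeling density per punctum unchanged,
  # dimmer signal) or through punctum density (fewer ribosomes).
  fig1-kd-puro:
    kind: pair
    scale_factor: 0.71        # test group at 71% of control -> 29% reduction
    scale_target: photon_scale
    geometry: {length_um: 30, width_nm: 500}
    scene:
      n_puncta: 150
      bound_fraction: 0
      bind_distance_nm: 0
      er_tubule_radius_nm: 60
    render:
      pixel_size_nm: 100
      psf_fwhm_nm: 250
      photon_scale: 200
      read_noise_sd: 2
      background_level: 10
      margin_nm: 600
    quantify: {width_px: 5, background_rows: 2}

  fig1-removal-puro:
    kind: pair
    scale_factor: 0.70        # 30% reduction after axonal ER removal
    scale_target: photon_scale
    geometry: {length_um: 30, width_nm: 500}
    scene:
      n_puncta: 150
      bound_fraction: 0
      bind_distance_nm: 0
      er_tubule_radius_nm: 60
    render:
      pixel_size_nm: 100
      psf_fwhm_nm: 250
      photon_scale: 200
      read_noise_sd: 2
      background_level: 10
      margin_nm: 600
    quantify: {width_px: 5, background_rows: 2}

  fig1-kd-rps12:
    kind: pair
    scale_factor: 0.63        # 37% fewer ribosomal puncta
    scale_target: n_puncta
    geometry: {length_um: 30, width_nm: 500}
    scene:
      n_puncta: 300
      bound_fraction: 0
      bind_distance_nm: 0
      er_tubule_radius_nm: 60
    render:
      pixel_size_nm: 100
      psf_fwhm_nm: 250
      photon_scale: 150
      read_noise_sd: 2
      background_level: 10
      margin_nm: 600
    quantify: {width_px: 5, background_rows: 2}

  # STED-like contact geometry: bound fraction mid-range of the printed
  # 40%-50% band; binding shell 30 nm; PSF 60 nm FWHM sampled at 20 nm.
  # Tubule radius, coverage, photon levels and axon width are simulator
  # conventions chosen so the estimator's operating point sits inside the
  # printed band (the study reports the measured proportion, not the
  # underlying geometry).
  fig2-sted-contact:
    kind: contact
    geometry: {length_um: 10, width_nm: 340}
    scene:
      n_puncta: 80
      bound_fraction: 0.45
      bind_distance_nm: 30
      er_tubule_radius_nm: 100
      er_coverage: 0.62
      er_segment_um: 1.0
    render:
      pixel_size_nm: 20
      psf_fwhm_nm: 60
      photon_scale: 120
      photon_scale_er: 150
      read_noise_sd: 1
      background_level: 1.2
      margin_nm: 0
    quantify: {dilate_nm: 5, threshold: otsu}

  # Split-APEX streptavidin signal along a branched axon: punctum density in
  # 2 um windows centered on branch points is 1.75x the shaft density.
  fig3-branch:
    kind: branch
    geometry: {length_um: 30, width_nm: 500, n_branches: 3}
    scene:
      n_puncta: 700
      bound_fraction: 0
      bind_distance_nm: 0
      er_tubule_radius_nm: 60
      branch_density_factor: 1.75
      branch_window_um: 2
    render:
      pixel_size_nm: 100
      psf_fwhm_nm: 250
      photon_scale: 150
      read_noise_sd: 2
      background_level: 10
      margin_nm: 600
    # the measured branch window is inset to the central 1.5 um of the 2 um
    # enrichment zone so the PSF-blurred density transition at the window
    # edges does not dilute the branch measure
    quantify: {width_px: 5, background_rows: 2, branch_window_um: 1.5, guard_um: 1}
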