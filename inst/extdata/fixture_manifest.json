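[{"file":"movie_fos_btg2.tif","md5":"9076b7a763f8d3f80d286032d53581f4"},{"file":"movie_fos_btg2.tif.json","md5":"307d41035b37d34021e3cde3c06389d5"},{"file":"movie_fos_btg2.tif.truth.csv","md5":"3951e815765a402c9e9b11b10c55c16c"},{"file":"traj_and_gate.csv","md5":"094cd382ed92b2313bd6b16f4090de6b"},{"file":"traj_btg2_btg2.csv","md5":"23bfa81437c5f33deb413e285202e1be"},{"file":"traj_btg2_fos.csv","md5":"d597b1f02c23d728e754374bd7810189"},{"file":"traj_fos_btg2.csv","md5":"23bfa81437c5f33deb413e285202e1be"},{"file":"traj_fos_fos.csv","md5":"d597b1f02c23d728e754374bd7810189"},{"file":"traj_fos_fra1deg_fos.csv","md5":"d53639d97f370354d2e81d2179e6e742"},{"file":"traj_fos_tubulin.csv","md5":"3a934d0750f58b786abbb81092e35565"}]
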