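E46 -0.892539 -0.416198 -0.173648
E50 -0.791240 -0.554032 -0.258819
E51 -0.818653 -0.573227 0.034899
E56 -0.640856 -0.640856 -0.422618
E57 -0.628741 -0.749305 -0.207912
E58 -0.641907 -0.764995 0.052336
E59 -0.495134 -0.857597 0.139173
E63 -0.463592 -0.802965 -0.374607
E64 -0.416198 -0.892539 -0.173648
E65 -0.342020 -0.939693 0.000000
E66 -0.254887 -0.951251 0.173648
E68 -0.246152 -0.918650 -0.309017
E69 -0.137819 -0.980631 -0.139173
E102 0.892539 -0.416198 -0.173648
E101 0.791240 -0.554032 -0.258819
E97 0.818653 -0.573227 0.034899
E107 0.640856 -0.640856 -0.422618
E100 0.628741 -0.749305 -0.207912
E96 0.641907 -0.764995 0.052336
E91 0.495134 -0.857597 0.139173
E99 0.463592 -0.802965 -0.374607
E95 0.416198 -0.892539 -0.173648
E90 0.342020 -0.939693 0.000000
E84 0.254887 -0.951251 0.173648
E94 0.246152 -0.918650 -0.309017
E89 0.137819 -0.980631 -0.139173
F01 -0.710106 -0.650515 0.269407
F02 0.083653 0.953186 0.290584
F03 0.578115 -0.754048 0.311761
F04 -0.928535 0.164245 0.332937
F05 0.789082 0.501949 0.354114
F06 -0.240629 -0.895128 0.375290
F07 -0.423135 0.814721 0.396467
F08 0.853478 -0.311689 0.417644
F09 -0.830594 -0.342857 0.438820
F10 0.376342 0.804220 0.459997
F11 0.262360 -0.836445 0.481173
F12 -0.748117 0.433549 0.502350
F13 0.832137 0.182943 0.523527
F14 -0.482320 -0.686051 0.544703
F15 -0.105955 0.817651 0.565880
F16 0.619019 -0.521710 0.587056
F17 -0.793081 -0.032796 0.608233
F18 0.550813 0.548132 0.629410
F19 -0.035079 -0.758622 0.650586
F20 -0.474616 0.568748 0.671763
F21 0.714557 -0.096143 0.692939
F22 -0.574623 -0.399808 0.714116
F23 0.148753 0.661224 0.735293
F24 0.325171 -0.567467 0.756469
F25 -0.598961 0.191085 0.777646
F26 0.546097 0.252311 0.798822
F27 -0.220968 -0.527991 0.819999
F28 -0.183022 0.508848 0.841176
F29 0.448179 -0.235551 0.862352
F30 -0.452907 -0.119385 0.883529
F31 0.230417 0.358352 0.904705
F32 0.063993 -0.372354 0.925882
F33 -0.253838 0.196587 0.947059
F34 0.249188 0.020645 0.968235
F35 -0.098559 -0.106539 0.989412
nasion 0.000000 0.965926 -0.258819
lpa -0.939693 0.000000 -0.342020
rpa 0.939693 0.000000 -0.342020
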