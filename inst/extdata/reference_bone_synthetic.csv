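"sex","age_yr","bmc_tb_mean","bmc_tb_sd","bmd_tb_mean","bmd_tb_sd","bmd_ls_mean","bmd_ls_sd","bmd_tblh_mean","bmd_tblh_sd"
"F",5,760,114,0.84,0.07,0.685,0.08,0.7,0.07
"F",5.5,807.5,121.1,0.854,0.07,0.7025,0.08,0.715,0.07
"F",6,855,128.2,0.868,0.07,0.72,0.08,0.73,0.07
"F",6.5,902.5,135.4,0.882,0.07,0.7375,0.08,0.745,0.07
"F",7,950,142.5,0.896,0.07,0.755,0.08,0.76,0.07
"F",7.5,997.5,149.6,0.91,0.07,0.7725,0.08,0.775,0.07
"F",8,1045,156.8,0.924,0.07,0.79,0.08,0.79,0.07
"F",8.5,1092.5,163.9,0.938,0.07,0.8075,0.08,0.805,0.07
"F",9,1140,171,0.952,0.07,0.825,0.08,0.82,0.07
"F",9.5,1187.5,178.1,0.966,0.07,0.8425,0.08,0.835,0.07
"F",10,1235,185.2,0.98,0.07,0.86,0.08,0.85,0.07
"F",10.5,1282.5,192.4,0.994,0.07,0.8775,0.08,0.865,0.07
"F",11,1330,199.5,1.008,0.07,0.895,0.08,0.88,0.07
"F",11.5,1377.5,206.6,1.022,0.07,0.9125,0.08,0.895,0.07
"F",12,1425,213.8,1.036,0.07,0.93,0.08,0.91,0.07
"F",12.5,1472.5,220.9,1.05,0.07,0.9475,0.08,0.925,0.07
"F",13,1520,228,1.064,0.07,0.965,0.08,0.94,0.07
"F",13.5,1567.5,235.1,1.078,0.07,0.9825,0.08,0.955,0.07
"M",5,775,116.2,0.84,0.07,0.675,0.08,0.7,0.07
"M",5.5,822.5,123.4,0.854,0.07,0.6925,0.08,0.715,0.07
"M",6,870,130.5,0.868,0.07,0.71,0.08,0.73,0.07
"M",6.5,917.5,137.6,0.882,0.07,0.7275,0.08,0.745,0.07
"M",7,965,144.8,0.896,0.07,0.745,0.08,0.76,0.07
"M",7.5,1012.5,151.9,0.91,0.07,0.7625,0.08,0.775,0.07
"M",8,1060,159,0.924,0.07,0.78,0.08,0.79,0.07
"M",8.5,1107.5,166.1,0.938,0.07,0.7975,0.08,0.805,0.07
"M",9,1155,173.2,0.952,0.07,0.815,0.08,0.82,0.07
"M",9.5,1202.5,180.4,0.966,0.07,0.8325,0.08,0.835,0.07
"M",10,1250,187.5,0.98,0.07,0.85,0.08,0.85,0.07
"M",10.5,1297.5,194.6,0.994,0.07,0.8675,0.08,0.865,0.07
"M",11,1345,201.8,1.008,0.07,0.885,0.08,0.88,0.07
"M",11.5,1392.5,208.9,1.022,0.07,0.9025,0.08,0.895,0.07
"M",12,1440,216,1.036,0.07,0.92,0.08,0.91,0.07
"M",12.5,1487.5,223.1,1.05,0.07,0.9375,0.08,0.925,0.07
"M",13,1535,230.2,1.064,0.07,0.955,0.08,0.94,0.07
"M",13.5,1582.5,237.4,1.078,0.07,0.9725,0.08,0.955,0.07
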