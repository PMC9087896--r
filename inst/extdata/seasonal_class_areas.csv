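season,date,segmentation,class,area_km2
summer,2000.06,fvc,BL&W,366.27
summer,2000.06,fvc,L-FVC,1130.73
summer,2000.06,fvc,SL-FVC,1872.23
summer,2000.06,fvc,M-FVC,1178.33
summer,2000.06,fvc,H-FVC,1443.78
summer,2005.06,fvc,BL&W,611.89
summer,2005.06,fvc,L-FVC,1042.845
summer,2005.06,fvc,SL-FVC,1462.21
summer,2005.06,fvc,M-FVC,1166.90
summer,2005.06,fvc,H-FVC,1802.48
summer,2009.07,fvc,BL&W,1823.94
summer,2009.07,fvc,L-FVC,810.22
summer,2009.07,fvc,SL-FVC,1090.41
summer,2009.07,fvc,M-FVC,1320.57
summer,2009.07,fvc,H-FVC,1116.84
summer,2015.07,fvc,BL&W,617.73
summer,2015.07,fvc,L-FVC,1159.76
summer,2015.07,fvc,SL-FVC,1379.00
summer,2015.07,fvc,M-FVC,1279.08
summer,2015.07,fvc,H-FVC,1750.11
summer,2020.06,fvc,BL&W,540.87
summer,2020.06,fvc,L-FVC,998.00
summer,2020.06,fvc,SL-FVC,1394.44
summer,2020.06,fvc,M-FVC,1344.36
summer,2020.06,fvc,H-FVC,1908.04
winter,2000.12,fvc,BL&W,508.29
winter,2000.12,fvc,L-FVC,1479.30
winter,2000.12,fvc,SL-FVC,2026.24
winter,2000.12,fvc,M-FVC,1114.43
winter,2000.12,fvc,H-FVC,863.08
winter,2005.01,fvc,BL&W,603.30
winter,2005.01,fvc,L-FVC,1717.48
winter,2005.01,fvc,SL-FVC,1674.91
winter,2005.01,fvc,M-FVC,862.25
winter,2005.01,fvc,H-FVC,1228.40
winter,2010.12,fvc,BL&W,722.36
winter,2010.12,fvc,L-FVC,1732.53
winter,2010.12,fvc,SL-FVC,1807.00
winter,2010.12,fvc,M-FVC,800.94
winter,2010.12,fvc,H-FVC,1099.43
winter,2016.01,fvc,BL&W,1197.54
winter,2016.01,fvc,L-FVC,2057.59
winter,2016.01,fvc,SL-FVC,1534.55
winter,2016.01,fvc,M-FVC,652.84
winter,2016.01,fvc,H-FVC,743.18
winter,2020.12,fvc,BL&W,948.63
winter,2020.12,fvc,L-FVC,844.41
winter,2020.12,fvc,SL-FVC,1307.38
winter,2020.12,fvc,M-FVC,1259.15
winter,2020.12,fvc,H-FVC,1826.06
summer,2000.06,lst,HTZ,906.36
summer,2000.06,lst,SHTZ,982.81
summer,2000.06,lst,MTZ,2619.26
summer,2000.06,lst,SLTZ,657.43
summer,2000.06,lst,LTZ,825.51
summer,2005.06,lst,HTZ,785.27
summer,2005.06,lst,SHTZ,1280.25
summer,2005.06,lst,MTZ,2657.49
summer,2005.06,lst,SLTZ,561.73
summer,2005.06,lst,LTZ,801.60
summer,2009.07,lst,HTZ,952.79
summer,2009.07,lst,SHTZ,737.38
summer,2009.07,lst,MTZ,2773.14
summer,2009.07,lst,SLTZ,1087.06
summer,2009.07,lst,LTZ,611.91
summer,2015.07,lst,HTZ,1008.44
summer,2015.07,lst,SHTZ,1008.75
summer,2015.07,lst,MTZ,2284.25
summer,2015.07,lst,SLTZ,898.59
summer,2015.07,lst,LTZ,985.69
summer,2020.06,lst,HTZ,907.56
summer,2020.06,lst,SHTZ,1093.14
summer,2020.06,lst,MTZ,2479.23
summer,2020.06,lst,SLTZ,899.82
summer,2020.06,lst,LTZ,805.97
winter,2000.12,lst,HTZ,809.12
winter,2000.12,lst,SHTZ,814.85
winter,2000.12,lst,MTZ,2338.86
winter,2000.12,lst,SLTZ,1490.14
winter,2000.12,lst,LTZ,530.20
winter,2005.01,lst,HTZ,522.25
winter,2005.01,lst,SHTZ,1359.04
winter,2005.01,lst,MTZ,2993.18
winter,2005.01,lst,SLTZ,542.83
winter,2005.01,lst,LTZ,669.12
winter,2010.12,lst,HTZ,808.89
winter,2010.12,lst,SHTZ,1238.82
winter,2010.12,lst,MTZ,2650.40
winter,2010.12,lst,SLTZ,925.88
winter,2010.12,lst,LTZ,538.31
winter,2016.01,lst,HTZ,824.99
winter,2016.01,lst,SHTZ,1338.22
winter,2016.01,lst,MTZ,2504.20
winter,2016.01,lst,SLTZ,764.66
winter,2016.01,lst,LTZ,735.65
winter,2020.12,lst,HTZ,705.17
winter,2020.12,lst,SHTZ,1017.44
winter,2020.12,lst,MTZ,3361.66
winter,2020.12,lst,SLTZ,581.63
winter,2020.12,lst,LTZ,519.81
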