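site_id,month,temperature,precipitation,pet
S001,1,-17.21,14.04,0
S001,2,-15.91,14.85,0
S001,3,-12.36,17.05,0
S001,4,-7.51,20.06,0
S001,5,-2.66,23.07,20.38
S001,6,0.89,25.27,39.91
S001,7,2.19,26.08,47.06
S001,8,0.89,25.27,39.91
S001,9,-2.66,23.07,20.38
S001,10,-7.51,20.06,0
S001,11,-12.36,17.05,0
S001,12,-15.91,14.85,0
S002,1,28.67,204.44,192.7
S002,2,28.56,198.12,192.06
S002,3,28.24,180.85,190.29
S002,4,27.8,157.26,187.88
S002,5,27.36,133.67,185.47
S002,6,27.04,116.4,183.71
S002,7,26.92,110.08,183.06
S002,8,27.04,116.4,183.71
S002,9,27.36,133.67,185.47
S002,10,27.8,157.26,187.88
S002,11,28.24,180.85,190.29
S002,12,28.56,198.12,192.06
S003,1,2.79,41.31,50.33
S003,2,3.49,43.68,54.22
S003,3,5.42,50.16,64.83
S003,4,8.06,59.01,79.32
S003,5,10.69,67.87,93.82
S003,6,12.62,74.35,104.43
S003,7,13.33,76.72,108.31
S003,8,12.62,74.35,104.43
S003,9,10.69,67.87,93.82
S003,10,8.06,59.01,79.32
S003,11,5.42,50.16,64.83
S003,12,3.49,43.68,54.22
S004,1,-11.84,27.07,0
S004,2,-9.77,28.63,0
S004,3,-4.1,32.87,12.42
S004,4,3.64,38.68,54.99
S004,5,11.37,44.48,97.56
S004,6,17.04,48.72,128.72
S004,7,19.11,50.28,140.13
S004,8,17.04,48.72,128.72
S004,9,11.37,44.48,97.56
S004,10,3.64,38.68,54.99
S004,11,-4.1,32.87,12.42
S004,12,-9.77,28.63,0
S005,1,-12.75,26.59,0
S005,2,-10.34,28.12,0
S005,3,-3.77,32.29,14.26
S005,4,5.2,37.99,63.62
S005,5,14.18,43.68,112.99
S005,6,20.75,47.86,149.13
S005,7,23.16,49.38,162.36
S005,8,20.75,47.86,149.13
S005,9,14.18,43.68,112.99
S005,10,5.2,37.99,63.62
S005,11,-3.77,32.29,14.26
S005,12,-10.34,28.12,0
S006,1,-11.65,41.06,0
S006,2,-9.71,43.42,0
S006,3,-4.42,49.86,10.72
S006,4,2.82,58.66,50.51
S006,5,10.06,67.45,90.31
S006,6,15.35,73.9,119.44
S006,7,17.29,76.25,130.1
S006,8,15.35,73.9,119.44
S006,9,10.06,67.45,90.31
S006,10,2.82,58.66,50.51
S006,11,-4.42,49.86,10.72
S006,12,-9.71,43.42,0
S007,1,26.06,200.61,178.34
S007,2,25.88,194.41,177.37
S007,3,25.4,177.46,174.71
S007,4,24.74,154.31,171.09
S007,5,24.09,131.17,167.47
S007,6,23.6,114.22,164.82
S007,7,23.43,108.02,163.85
S007,8,23.6,114.22,164.82
S007,9,24.09,131.17,167.47
S007,10,24.74,154.31,171.09
S007,11,25.4,177.46,174.71
S007,12,25.88,194.41,177.37
S008,1,-12.9,51.11,0
S008,2,-10.72,54.04,0
S008,3,-4.77,62.06,8.79
S008,4,3.37,73.01,53.52
S008,5,11.5,83.96,98.26
S008,6,17.46,91.98,131
S008,7,19.63,94.91,142.99
S008,8,17.46,91.98,131
S008,9,11.5,83.96,98.26
S008,10,3.37,73.01,53.52
S008,11,-4.77,62.06,8.79
S008,12,-10.72,54.04,0
S009,1,20.22,96.14,146.19
S009,2,19.39,93.17,141.65
S009,3,17.14,85.05,129.26
S009,4,14.06,73.96,112.32
S009,5,10.98,62.86,95.39
S009,6,8.73,54.74,82.99
S009,7,7.9,51.77,78.45
S009,8,8.73,54.74,82.99
S009,9,10.98,62.86,95.39
S009,10,14.06,73.96,112.32
S009,11,17.14,85.05,129.26
S009,12,19.39,93.17,141.65
S010,1,-14.11,27.81,0
S010,2,-11.98,29.4,0
S010,3,-6.19,33.77,0.98
S010,4,1.73,39.73,44.54
S010,5,9.65,45.68,88.1
S010,6,15.45,50.05,119.99
S010,7,17.57,51.64,131.66
S010,8,15.45,50.05,119.99
S010,9,9.65,45.68,88.1
S010,10,1.73,39.73,44.54
S010,11,-6.19,33.77,0.98
S010,12,-11.98,29.4,0
S011,1,21.14,170.84,151.29
S011,2,20.44,165.56,147.41
S011,3,18.51,151.13,136.83
S011,4,15.88,131.42,122.36
S011,5,13.25,111.7,107.9
S011,6,11.33,97.27,97.31
S011,7,10.62,91.99,93.43
S011,8,11.33,97.27,97.31
S011,9,13.25,111.7,107.9
S011,10,15.88,131.42,122.36
S011,11,18.51,151.13,136.83
S011,12,20.44,165.56,147.41
S012,1,-16.88,37.25,0
S012,2,-14.57,39.39,0
S012,3,-8.25,45.23,0
S012,4,0.38,53.21,37.11
S012,5,9.02,61.19,84.59
S012,6,15.34,67.04,119.35
S012,7,17.65,69.18,132.07
S012,8,15.34,67.04,119.35
S012,9,9.02,61.19,84.59
S012,10,0.38,53.21,37.11
S012,11,-8.25,45.23,0
S012,12,-14.57,39.39,0
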